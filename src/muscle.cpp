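#include "muscle.h"

using namespace arma;

namespace flexgait {

static const double FL_C = std::log(0.05);  // f_l value at the curve edges

double fl_curve(const MTU& m, double lce) {
  double x = std::fabs((lce - m.lopt) / (m.lopt * m.w));
  return std::exp(FL_C * x * x * x);
}

double fv_curve(const MTU& m, double vce) {
  if (vce <= 0.0) {
    double v = std::max(vce, -m.vmax);
    return (m.vmax + v) / (m.vmax - m.fvK * v);
  }
  double ce = 7.56 * m.fvK;
  return m.fvN - (m.fvN - 1.0) / (1.0 + ce * vce / m.vmax);
}

double fv_inverse(const MTU& m, double fv) {
  if (fv <= 0.0) return -m.vmax;
  if (fv <= 1.0) return m.vmax * (fv - 1.0) / (1.0 + m.fvK * fv);
  double ce = 7.56 * m.fvK;
  double f = std::min(fv, m.fvN - 1e-3);
  return m.vmax * ((m.fvN - 1.0) / (m.fvN - f) - 1.0) / ce;
}

double fse_curve(const MTU& m, double lse) {
  double eps = (lse - m.lslack) / m.lslack;
  if (eps <= 0.0) return 0.0;
  double r = eps / m.epsref;
  return m.Fmax * r * r;
}

double fpe_curve(const MTU& m, double lce) {
  // engages half a force-length width beyond optimal length, so the
  // passive elements stay silent over the normal operating range
  double l0 = m.lopt * (1.0 + 0.5 * m.w);
  if (lce <= l0) return 0.0;
  double x = (lce - l0) / (m.lopt * m.w);
  return m.Fmax * x * x;
}

double fbe_curve(const MTU& m, double lce) {
  double lmin = m.lopt * (1.0 - m.w);
  if (lce >= lmin) return 0.0;
  double x = (lmin - lce) / (m.lopt * m.w * 0.5);
  return m.Fmax * x * x;
}

double mtu_length(const MTU& m, const vec& qleg) {
  double l = m.lopt + m.lslack;
  for (int a = 0; a < m.ndof; ++a) {
    double th = qleg(m.dof[a]);
    if (std::isnan(m.thmax[a])) {
      l -= m.sgn[a] * m.r0[a] * (th - m.thref[a]);
    } else {
      l -= m.sgn[a] * m.r0[a] *
           (std::sin(th - m.thmax[a]) - std::sin(m.thref[a] - m.thmax[a]));
    }
  }
  return l;
}

void mtu_arms(const MTU& m, const vec& qleg, double* arm_out) {
  for (int a = 0; a < m.ndof; ++a) {
    double th = qleg(m.dof[a]);
    arm_out[a] = std::isnan(m.thmax[a])
                     ? m.sgn[a] * m.r0[a]
                     : m.sgn[a] * m.r0[a] * std::cos(th - m.thmax[a]);
  }
}

double mtu_velocity(const MTU& m, const vec& qleg, const vec& qdleg) {
  double arms[2];
  mtu_arms(m, qleg, arms);
  double v = 0.0;
  for (int a = 0; a < m.ndof; ++a) v -= arms[a] * qdleg(m.dof[a]);
  return v;
}

MtuForces mtu_equilibrium(const MTU& m, double lce, double act, double lmtu) {
  MtuForces out;
  double lse = lmtu - lce;
  out.Fse = fse_curve(m, lse);
  out.Fpe = fpe_curve(m, lce);
  out.Fbe = fbe_curve(m, lce);
  out.fl = fl_curve(m, lce);
  double Fce_req = out.Fse - out.Fpe + out.Fbe;
  double denom = std::max(act, 0.005) * m.Fmax * std::max(out.fl, 0.01);
  double fv = Fce_req / denom;
  out.vce = fv_inverse(m, fv);
  out.fv = fv_curve(m, out.vce);
  out.Fce = Fce_req;
  return out;
}

mat moment_arm_matrix(const MuscleSet& ms, const vec& q) {
  mat C(14, ms.n(), fill::zeros);
  for (int j = 0; j < ms.n(); ++j) {
    const MTU& m = ms.mus[j];
    int base = 6 + 4 * m.leg;
    vec qleg = q.subvec(base, base + 3);
    double arms[2];
    mtu_arms(m, qleg, arms);
    for (int a = 0; a < m.ndof; ++a) C(base + m.dof[a], j) = arms[a];
  }
  return C;
}

MuscleSet muscles_from_list(const Rcpp::List& tbl) {
  MuscleSet ms;
  Rcpp::IntegerVector leg = tbl["leg"], ndof = tbl["ndof"], dof1 = tbl["dof1"],
                      dof2 = tbl["dof2"];
  Rcpp::NumericVector Fmax = tbl["Fmax"], lopt = tbl["lopt"],
                      lslack = tbl["lslack"], vmax = tbl["vmax"], w = tbl["w"],
                      fvN = tbl["fvN"], fvK = tbl["fvK"],
                      epsref = tbl["epsref"], tauA = tbl["tauA"],
                      r1 = tbl["r1"], thmax1 = tbl["thmax1"],
                      thref1 = tbl["thref1"], sgn1 = tbl["sgn1"],
                      r2 = tbl["r2"], thmax2 = tbl["thmax2"],
                      thref2 = tbl["thref2"], sgn2 = tbl["sgn2"];
  int n = leg.size();
  for (int i = 0; i < n; ++i) {
    MTU m;
    m.leg = leg[i];
    m.Fmax = Fmax[i];
    m.lopt = lopt[i];
    m.lslack = lslack[i];
    m.vmax = vmax[i];
    m.w = w[i];
    m.fvN = fvN[i];
    m.fvK = fvK[i];
    m.epsref = epsref[i];
    m.tauA = tauA[i];
    m.ndof = ndof[i];
    m.dof[0] = dof1[i];
    m.r0[0] = r1[i];
    m.thmax[0] = thmax1[i];
    m.thref[0] = thref1[i];
    m.sgn[0] = sgn1[i];
    m.dof[1] = dof2[i] < 0 ? 0 : dof2[i];
    m.r0[1] = r2[i];
    m.thmax[1] = thmax2[i];
    m.thref[1] = thref2[i];
    m.sgn[1] = sgn2[i];
    ms.mus.push_back(m);
  }
  return ms;
}

}  // namespace flexgait
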