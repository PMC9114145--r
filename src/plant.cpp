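#include "plant.h"

using namespace arma;

namespace flexgait {

static m3 rot_axis(const v3& a, double th) {
  // active rotation by th about unit axis a
  m3 K = {{0, -a(2), a(1)}, {a(2), 0, -a(0)}, {-a(1), a(0), 0}};
  m3 I = eye(3, 3);
  return I + std::sin(th) * K + (1.0 - std::cos(th)) * (K * K);
}

void fk(Plant& P, const vec& q) {
  for (int i = 0; i < Plant::NQ; ++i) {
    const Joint& J = P.joints[i];
    m3 Rp = (J.parent < 0) ? m3(eye(3, 3)) : P.Rw[J.parent];
    v3 pp = (J.parent < 0) ? v3(zeros(3)) : P.pw[J.parent];
    v3 pj = pp + Rp * J.ptree;
    if (J.type == 1) {
      P.Rw[i] = Rp * rot_axis(J.axis, q(i));
      P.pw[i] = pj;
    } else {
      P.Rw[i] = Rp;
      P.pw[i] = pj + Rp * (J.axis * q(i));
    }
  }
}

struct XForm { m3 E; v3 r; };  // v_child = E * (v - r x w) parts

static inline SpV xmot(const XForm& X, const SpV& v) {
  SpV o;
  o.ang = X.E * v.ang;
  o.lin = X.E * (v.lin - cross(X.r, v.ang));
  return o;
}

static inline SpF xforce_to_parent(const XForm& X, const SpF& f) {
  SpF o;
  v3 la = X.E.t() * f.ang;
  v3 ll = X.E.t() * f.lin;
  o.ang = la + cross(X.r, ll);
  o.lin = ll;
  return o;
}

static inline SpV crm(const SpV& v, const SpV& m) {
  SpV o;
  o.ang = cross(v.ang, m.ang);
  o.lin = cross(v.ang, m.lin) + cross(v.lin, m.ang);
  return o;
}

static inline SpF crf(const SpV& v, const SpF& f) {
  SpF o;
  o.ang = cross(v.ang, f.ang) + cross(v.lin, f.lin);
  o.lin = cross(v.ang, f.lin);
  return o;
}

static inline SpF imul(const Joint& J, const SpV& v) {
  SpF o;
  v3 vcom = v.lin + cross(v.ang, J.com);
  o.lin = J.mass * vcom;
  o.ang = J.Icom * v.ang + cross(J.com, o.lin);
  return o;
}

vec rnea(Plant& P, const vec& q, const vec& qd, const vec& qdd,
         const std::vector<SpF>* fext_world, bool gravity) {
  const int N = Plant::NQ;
  fk(P, q);
  SpV v[N], a[N];
  SpF f[N];
  XForm X[N];
  v3 S[N];
  for (int i = 0; i < N; ++i) {
    const Joint& J = P.joints[i];
    if (J.type == 1) {
      X[i].E = rot_axis(J.axis, q(i)).t();
      X[i].r = J.ptree;
    } else {
      X[i].E = eye(3, 3);
      X[i].r = J.ptree + J.axis * q(i);
    }
    SpV vp, ap;
    if (J.parent < 0) {
      vp.ang = zeros(3); vp.lin = zeros(3);
      ap.ang = zeros(3);
      ap.lin = gravity ? v3{0, 0, P.grav} : v3(zeros(3));
    } else {
      vp = v[J.parent];
      ap = a[J.parent];
    }
    v[i] = xmot(X[i], vp);
    a[i] = xmot(X[i], ap);
    SpV Sq;
    if (J.type == 1) { Sq.ang = J.axis * qd(i); Sq.lin = zeros(3); }
    else { Sq.ang = zeros(3); Sq.lin = J.axis * qd(i); }
    SpV vdofdd;
    if (J.type == 1) { vdofdd.ang = J.axis * qdd(i); vdofdd.lin = zeros(3); }
    else { vdofdd.ang = zeros(3); vdofdd.lin = J.axis * qdd(i); }
    v[i].ang += Sq.ang; v[i].lin += Sq.lin;
    SpV cor = crm(v[i], Sq);
    a[i].ang += vdofdd.ang + cor.ang;
    a[i].lin += vdofdd.lin + cor.lin;

    SpF Ia = imul(J, a[i]);
    SpF Iv = imul(J, v[i]);
    SpF cv = crf(v[i], Iv);
    f[i].ang = Ia.ang + cv.ang;
    f[i].lin = Ia.lin + cv.lin;
    if (fext_world) {
      // external spatial force given about body origin in world orientation
      const SpF& fw = (*fext_world)[i];
      f[i].ang -= P.Rw[i].t() * fw.ang;
      f[i].lin -= P.Rw[i].t() * fw.lin;
    }
  }
  vec tau(N);
  for (int i = N - 1; i >= 0; --i) {
    const Joint& J = P.joints[i];
    tau(i) = (J.type == 1) ? dot(J.axis, f[i].ang) : dot(J.axis, f[i].lin);
    if (J.parent >= 0) {
      SpF fp = xforce_to_parent(X[i], f[i]);
      f[J.parent].ang += fp.ang;
      f[J.parent].lin += fp.lin;
    }
  }
  return tau;
}

mat mass_matrix(Plant& P, const vec& q) {
  const int N = Plant::NQ;
  mat M(N, N);
  vec zero = zeros(N);
  for (int j = 0; j < N; ++j) {
    vec ej = zeros(N);
    ej(j) = 1.0;
    M.col(j) = rnea(P, q, zero, ej, nullptr, false);
  }
  return 0.5 * (M + M.t());
}

vec fwd_dyn(Plant& P, const vec& q, const vec& qd, const vec& tau,
            const std::vector<SpF>* fext_world, const uvec& active) {
  vec bias = rnea(P, q, qd, zeros(Plant::NQ), fext_world, true);
  mat M = mass_matrix(P, q);
  vec qdd = zeros(Plant::NQ);
  vec rhs = tau(active) - bias(active);
  mat Ma = M(active, active);
  vec x = solve(Ma, rhs, solve_opts::likely_sympd);
  qdd(active) = x;
  return qdd;
}

v3 body_point(const Plant& P, int body, const v3& plocal) {
  return P.pw[body] + P.Rw[body] * plocal;
}

v3 body_point_vel(Plant& P, int body, const vec& q, const vec& qd,
                  const v3& plocal) {
  // accumulate joint contributions in world frame directly
  int chain[Plant::NQ];
  int n = 0, i = body;
  while (i >= 0) { chain[n++] = i; i = P.joints[i].parent; }
  v3 w = zeros(3), vo = zeros(3);
  v3 org = P.pw[body];
  for (int k = n - 1; k >= 0; --k) {
    int j = chain[k];
    const Joint& J = P.joints[j];
    v3 ax_w = (J.parent < 0) ? J.axis : v3(P.Rw[J.parent] * J.axis);
    if (J.type == 1) {
      v3 pj = P.pw[j];
      w += ax_w * qd(j);
      vo += cross(ax_w * qd(j), org - pj);
    } else {
      vo += ax_w * qd(j);
    }
  }
  return vo + cross(w, P.Rw[body] * plocal);
}

mat foot_contact(Plant& P, int foot_body, const vec& q, const vec& qd,
                 SpF& fout) {
  mat out(P.cpts.n_rows, 7, fill::zeros);
  fout.ang = zeros(3);
  fout.lin = zeros(3);
  for (uword k = 0; k < P.cpts.n_rows; ++k) {
    v3 pl = P.cpts.row(k).t();
    v3 p = body_point(P, foot_body, pl);
    out(k, 0) = p(0); out(k, 1) = p(1); out(k, 2) = p(2);
    double pen = -p(2);
    if (pen <= 0) continue;
    v3 pv = body_point_vel(P, foot_body, q, qd, pl);
    double pendot = -pv(2);
    double fz = P.cp.kn * pen * (1.0 + P.cp.cn * pendot);
    if (fz < 0) fz = 0;
    double vtx = pv(0), vty = pv(1);
    double vt = std::sqrt(vtx * vtx + vty * vty);
    double ft = P.cp.mu * fz * std::tanh(vt / P.cp.vreg);
    double fx = 0, fy = 0;
    if (vt > 1e-12) { fx = -ft * vtx / vt; fy = -ft * vty / vt; }
    out(k, 3) = pen; out(k, 4) = fz; out(k, 5) = fx; out(k, 6) = fy;
    v3 F = {fx, fy, fz};
    fout.lin += F;
    fout.ang += cross(p - P.pw[foot_body], F);
  }
  return out;
}

vec limit_torques(const Plant& P, const vec& q, const vec& qd) {
  vec tau = zeros(Plant::NQ);
  for (int i = 6; i < Plant::NQ; ++i) {
    if (q(i) > P.lim_hi(i)) {
      tau(i) = -P.lim_k * (q(i) - P.lim_hi(i)) - P.lim_d * qd(i);
    } else if (q(i) < P.lim_lo(i)) {
      tau(i) = -P.lim_k * (q(i) - P.lim_lo(i)) - P.lim_d * qd(i);
    }
  }
  return tau;
}

static m3 diagI(const Rcpp::NumericVector& v) {
  m3 I = zeros(3, 3);
  I(0, 0) = v[0]; I(1, 1) = v[1]; I(2, 2) = v[2];
  return I;
}

Plant plant_from_list(const Rcpp::List& conf) {
  Plant P;
  P.grav = Rcpp::as<double>(conf["gravity"]);
  Rcpp::List trunk = conf["trunk"], thigh = conf["thigh"],
             shank = conf["shank"], foot = conf["foot"];
  double hw = Rcpp::as<double>(conf["hip_width"]) / 2.0;
  double lt = Rcpp::as<double>(thigh["length"]);
  double ls = Rcpp::as<double>(shank["length"]);

  // trunk free-body chain: 3 prismatic + yaw/pitch/roll
  v3 zero3 = zeros(3);
  m3 zeroI = zeros(3, 3);
  int types[6] = {0, 0, 0, 1, 1, 1};
  v3 axes6[6] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1},
                 {0, 0, 1}, {0, 1, 0}, {1, 0, 0}};
  for (int i = 0; i < 6; ++i) {
    P.joints[i].parent = i - 1;
    P.joints[i].type = types[i];
    P.joints[i].axis = axes6[i];
    P.joints[i].ptree = zero3;
    P.joints[i].mass = 0;
    P.joints[i].com = zero3;
    P.joints[i].Icom = zeroI;
  }
  P.joints[5].mass = Rcpp::as<double>(trunk["mass"]);
  P.joints[5].com = Rcpp::as<arma::vec>(trunk["com"]);
  P.joints[5].Icom = diagI(trunk["I"]);

  for (int leg = 0; leg < 2; ++leg) {
    int b = 6 + 4 * leg;          // hip pitch joint index
    double side = leg == 0 ? 1.0 : -1.0;  // left +y
    // hip pitch: flexion positive moves leg forward -> axis (0,-1,0)
    P.joints[b].parent = 5;
    P.joints[b].type = 1;
    P.joints[b].axis = {0, -1, 0};
    P.joints[b].ptree = {0, side * hw, 0};
    P.joints[b].mass = 0; P.joints[b].com = zero3; P.joints[b].Icom = zeroI;
    // hip roll: adduction (toward midline) positive
    P.joints[b + 1].parent = b;
    P.joints[b + 1].type = 1;
    P.joints[b + 1].axis = {-side, 0, 0};
    P.joints[b + 1].ptree = zero3;
    P.joints[b + 1].mass = Rcpp::as<double>(thigh["mass"]);
    P.joints[b + 1].com = {0, 0, -Rcpp::as<double>(thigh["com_offset"])};
    P.joints[b + 1].Icom = diagI(thigh["I"]);
    // knee: flexion positive (shank backward)
    P.joints[b + 2].parent = b + 1;
    P.joints[b + 2].type = 1;
    P.joints[b + 2].axis = {0, 1, 0};
    P.joints[b + 2].ptree = {0, 0, -lt};
    P.joints[b + 2].mass = Rcpp::as<double>(shank["mass"]);
    P.joints[b + 2].com = {0, 0, -Rcpp::as<double>(shank["com_offset"])};
    P.joints[b + 2].Icom = diagI(shank["I"]);
    // ankle: dorsiflexion positive (toes up)
    P.joints[b + 3].parent = b + 2;
    P.joints[b + 3].type = 1;
    P.joints[b + 3].axis = {0, -1, 0};
    P.joints[b + 3].ptree = {0, 0, -ls};
    P.joints[b + 3].mass = Rcpp::as<double>(foot["mass"]);
    P.joints[b + 3].com = Rcpp::as<arma::vec>(foot["com"]);
    P.joints[b + 3].Icom = diagI(foot["I"]);
  }

  Rcpp::List lim = conf["limits"];
  arma::vec lo = Rcpp::as<arma::vec>(lim["lo"]);  // length 4, per-leg pattern
  arma::vec hi = Rcpp::as<arma::vec>(lim["hi"]);
  P.lim_lo = zeros(Plant::NQ);
  P.lim_hi = zeros(Plant::NQ);
  for (int leg = 0; leg < 2; ++leg)
    for (int j = 0; j < 4; ++j) {
      P.lim_lo(6 + 4 * leg + j) = lo(j);
      P.lim_hi(6 + 4 * leg + j) = hi(j);
    }
  P.lim_k = Rcpp::as<double>(lim["k"]);
  P.lim_d = Rcpp::as<double>(lim["d"]);

  Rcpp::List cc = conf["contact"];
  P.cpts = Rcpp::as<arma::mat>(cc["points"]);
  P.cp.kn = Rcpp::as<double>(cc["kn"]);
  P.cp.cn = Rcpp::as<double>(cc["cn"]);
  P.cp.mu = Rcpp::as<double>(cc["mu"]);
  P.cp.vreg = Rcpp::as<double>(cc["vreg"]);
  P.trunk_h0 = Rcpp::as<double>(conf["trunk_h0"]);
  return P;
}

}  // namespace flexgait
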