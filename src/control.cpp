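#include "control.h"

using namespace arma;

namespace flexgait {

vec minjerk_coeffs(double x0, double v0, double a0, double x1, double v1,
                   double a1, double T) {
  vec a(6);
  a(0) = x0;
  a(1) = v0;
  a(2) = 0.5 * a0;
  double T2 = T * T, T3 = T2 * T, T4 = T3 * T, T5 = T4 * T;
  double D = x1 - (x0 + v0 * T + 0.5 * a0 * T2);
  double V = v1 - (v0 + a0 * T);
  double A = a1 - a0;
  // solve [T3 T4 T5; 3T2 4T3 5T4; 6T 12T2 20T3] [a3 a4 a5]' = [D V A]'
  mat33 Mm = {{T3, T4, T5}, {3 * T2, 4 * T3, 5 * T4}, {6 * T, 12 * T2, 20 * T3}};
  vec3 rhs = {D, V, A};
  vec3 sol = solve(Mm, rhs);
  a(3) = sol(0);
  a(4) = sol(1);
  a(5) = sol(2);
  return a;
}

void minjerk_eval(const vec& a, double t, double& x, double& v, double& acc) {
  x = a(0) + t * (a(1) + t * (a(2) + t * (a(3) + t * (a(4) + t * a(5)))));
  v = a(1) + t * (2 * a(2) + t * (3 * a(3) + t * (4 * a(4) + t * 5 * a(5))));
  acc = 2 * a(2) + t * (6 * a(3) + t * (12 * a(4) + t * 20 * a(5)));
}

double stretch_reflex(double lce_hat, double vce_hat, double u, double udot,
                      double Kl, double Kv, double h, double Smin) {
  double S = Kl * (lce_hat + u) + Kv * (vce_hat + udot) - h;
  if (S < 0.0) S = 0.0;
  if (S < Smin) S = Smin;
  if (S > 1.0) S = 1.0;
  return S;
}

vec distribute_forces(const mat& C, const vec& tau, int niter) {
  mat Cp;
  if (!pinv(Cp, C, 1e-10)) Cp = pinv(C);  // fall back to default tolerance
  vec F = zeros(C.n_cols);
  vec t = tau;
  for (int it = 0; it < niter; ++it) {
    vec Fi = Cp * t;
    vec Fpos = clamp(Fi, 0.0, datum::inf);
    vec Fneg = Fi - Fpos;
    F += Fpos;
    if (norm(Fneg, 2) < 1e-12) break;
    // torque still missing after discarding the negative (non-physical)
    // part; re-distribute it in the next pass
    t = C * Fneg;
  }
  return F;
}

bool LegFsm::update(double t, bool ipsi_contact, bool contra_contact,
                    double t_early) {
  switch (phase) {
    case STANCE:
      if (contra_contact) {
        phase = EARLY_SWING;
        t_entry = t;
        return true;
      }
      break;
    case EARLY_SWING:
      if (t - t_entry >= t_early) {
        phase = LATE_SWING;
        t_entry = t;
        return true;
      }
      break;
    case LATE_SWING:
      if (ipsi_contact) {
        phase = STANCE;
        t_entry = t;
        return true;
      }
      break;
  }
  return false;
}

double balance_target(double phi0, double cd, double cv, double d_hat,
                      double v_hat, double phi_trunk_hat) {
  return (phi0 + cd * d_hat + cv * v_hat) - phi_trunk_hat;
}

vec stance_module_stims(const StanceGains& g, const StanceSignals& s) {
  enum { HFL = 0, GLU, HAM, RF, VAS, BFSH, GAS, SOL, TA, HAB, HAD };
  vec S(11);
  S.fill(g.Smin);
  double lam = std::min(std::max(s.load, 0.0), 1.0);
  // (1) compliant, spring-like leg: positive force feedback on extensors
  S(VAS) += g.g1_vas * s.Fn_vas;
  S(SOL) += g.g1_sol * s.Fn_sol;
  S(GAS) += g.g1_gas * s.Fn_gas;
  // (2) knee overextension prevention: suppress VAS and recruit BFSH only
  // while the knee is near full extension AND still extending
  double over = g.ko_phi - s.knee;
  if (over > 0 && s.dknee < 0) {
    S(VAS) -= g.ko_vas * over * (-s.dknee);
    S(BFSH) += g.ko_bfsh * over * (-s.dknee);
  }
  // (3) trunk-upright PD distributed to hip muscles, weighted by leg load
  double pd_s = g.gp_s * (s.pitch - g.th_ref_s) + g.gd_s * s.dpitch;
  if (pd_s > 0) {
    S(GLU) += lam * pd_s;
    S(HAM) += 0.5 * lam * pd_s;
  } else {
    S(HFL) += lam * (-pd_s);
  }
  double pd_f = g.gp_f * s.roll_rel + g.gd_f * s.droll_rel;
  if (pd_f > 0)
    S(HAB) += lam * pd_f;
  else
    S(HAD) += lam * (-pd_f);
  // (4) swing-leg interaction compensation at the stance hip
  double tsw = s.tau_sw_hip / 100.0;
  if (tsw > 0)
    S(GLU) += g.g4 * tsw;
  else
    S(HFL) += g.g4 * (-tsw);
  // (5) ankle dorsiflexion: TA length feedback, suppressed by SOL force
  double sta = g.g_ta * (s.lce_ta_norm - g.loff_ta) - g.gsup_ta * s.Fn_sol;
  S(TA) += std::max(0.0, sta);
  return clamp(S, g.Smin, 1.0);
}

}  // namespace flexgait
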