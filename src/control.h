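#ifndef FLEXGAIT_CONTROL_H
#define FLEXGAIT_CONTROL_H

#include <RcppArmadillo.h>
#include "plant.h"
#include "muscle.h"

namespace flexgait {

// ----- delay line: exact transport delay in control-step units -------------
struct DelayLine {
  std::vector<double> buf;
  int head = 0;
  int nd = 0;
  void init(int delay_steps, double x0) {
    nd = delay_steps < 0 ? 0 : delay_steps;
    buf.assign(nd + 1, x0);
    head = 0;
  }
  // push current sample, return sample from nd steps ago
  double step(double x) {
    if (nd == 0) return x;
    buf[head] = x;
    head = (head + 1) % (nd + 1);
    return buf[head];
  }
};

// ----- minimum-jerk planning ------------------------------------------------
// quintic coefficients a0..a5 for boundary states (x,v,a) at t=0 and t=T
arma::vec minjerk_coeffs(double x0, double v0, double a0, double x1, double v1,
                         double a1, double T);
// evaluate position / velocity / acceleration of a quintic at time t
void minjerk_eval(const arma::vec& a, double t, double& x, double& v,
                  double& acc);

// ----- generic stretch reflex (swing leg) -----------------------------------
double stretch_reflex(double lce_hat, double vce_hat, double u, double udot,
                      double Kl, double Kv, double h, double Smin);

// ----- iterative non-negative force distribution ----------------------------
// C: ndof x nmus moment-arm block, tau: desired torques.
// Returns F >= 0 (sum of positive parts over niter pseudo-inverse passes).
arma::vec distribute_forces(const arma::mat& C, const arma::vec& tau,
                            int niter);

// ----- behavioral finite state machine --------------------------------------
enum Phase { EARLY_SWING = 0, LATE_SWING = 1, STANCE = 2 };

struct LegFsm {
  Phase phase = STANCE;
  double t_entry = 0.0;
  // returns true if a transition happened at time t
  bool update(double t, bool ipsi_contact, bool contra_contact,
              double t_early);
};

// ----- balance law ----------------------------------------------------------
// phi_tilde = phi0 + cd*d + cv*v ; theta_hip = phi_tilde - phi_trunk
double balance_target(double phi0, double cd, double cv, double d_hat,
                      double v_hat, double phi_trunk_hat);

// ----- stance-leg reflex modules --------------------------------------------
// Five functional modules: (1) positive force feedback on anti-gravity
// extensors, (2) knee overextension prevention, (3) trunk-upright PD on hip
// muscles weighted by leg load, (4) compensation of swing-leg interaction
// torques, (5) ankle dorsiflexion by TA length feedback with plantarflexor
// suppression. Muscle order within the leg:
// HFL GLU HAM RF VAS BFSH GAS SOL TA HAB HAD.
struct StanceGains {
  double g1_vas, g1_sol, g1_gas;
  double ko_phi, ko_vas, ko_bfsh;
  double gp_s, gd_s, th_ref_s;
  double gp_f, gd_f;
  double g4, g_ta, loff_ta, gsup_ta;
  double Smin;
};
struct StanceSignals {
  double Fn_vas, Fn_sol, Fn_gas;  // delayed muscle forces / Fmax
  double knee, dknee;             // delayed knee angle and rate [rad, rad/s]
  double pitch, dpitch;           // delayed trunk pitch (forward +) and rate
  double roll_rel, droll_rel;     // delayed trunk roll toward this leg +
  double load;                    // leg load share in [0, 1]
  double tau_sw_hip;              // contralateral planned swing hip torque [Nm]
  double lce_ta_norm;             // delayed TA CE length / lopt
};
arma::vec stance_module_stims(const StanceGains& g, const StanceSignals& s);

}  // namespace flexgait

#endif
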