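// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "plant.h"
#include "muscle.h"
#include "control.h"

using namespace arma;
using namespace flexgait;
using Rcpp::List;
using Rcpp::Named;

namespace {

// ---------------------------------------------------------------------------
// shared controller plumbing
// ---------------------------------------------------------------------------

struct CtrlParams {
  double dt;         // physics step [s]
  int nsub;          // physics steps per control step
  vec Kl, Kv, h;     // per-muscle reflex gains (length n muscles)
  double Smin;
  ivec delay_mus;    // spindle/Golgi delay per muscle [control steps]
  ivec delay_q;      // joint state estimate delay per DoF [control steps]
  double flfv_floor; // denominator floor in the inverse muscle model
  int npinv;         // force-distribution iterations
  double udot_tau;   // first-order smoother for the command rate
  double freeze;     // replanning freeze window [s]
  double act0;       // initial muscle activation
  double acc_max;    // cap on commanded joint accelerations [rad/s^2]
  double acc_tau;    // smoother for the joint-acceleration estimate [s]
  double u_preview;  // lead time of the threshold command along the plan [s]
  double dtc() const { return dt * nsub; }
};

CtrlParams ctrl_from_list(const List& L) {
  CtrlParams c;
  c.dt = Rcpp::as<double>(L["dt"]);
  c.nsub = Rcpp::as<int>(L["nsub"]);
  c.Kl = Rcpp::as<vec>(L["Kl"]);
  c.Kv = Rcpp::as<vec>(L["Kv"]);
  c.h = Rcpp::as<vec>(L["h"]);
  c.Smin = Rcpp::as<double>(L["Smin"]);
  c.delay_mus = Rcpp::as<ivec>(L["delay_mus"]);
  c.delay_q = Rcpp::as<ivec>(L["delay_q"]);
  c.flfv_floor = Rcpp::as<double>(L["flfv_floor"]);
  c.npinv = Rcpp::as<int>(L["npinv"]);
  c.udot_tau = Rcpp::as<double>(L["udot_tau"]);
  c.freeze = Rcpp::as<double>(L["freeze"]);
  c.act0 = Rcpp::as<double>(L["act0"]);
  c.acc_max = Rcpp::as<double>(L["acc_max"]);
  c.acc_tau = Rcpp::as<double>(L["acc_tau"]);
  c.u_preview = Rcpp::as<double>(L["u_preview"]);
  return c;
}

struct MuscleStates {
  vec lce, act, vce, Fse;
};

MuscleStates init_muscles(const MuscleSet& ms, const vec& q, double act0) {
  MuscleStates st;
  int n = ms.n();
  st.lce = zeros(n);
  st.act = act0 * ones(n);
  st.vce = zeros(n);
  st.Fse = zeros(n);
  for (int i = 0; i < n; ++i) {
    const MTU& m = ms.mus[i];
    int base = 6 + 4 * m.leg;
    vec qleg = q.subvec(base, base + 3);
    double lm = mtu_length(m, qleg);
    st.lce(i) = std::max(lm - m.lslack, 0.5 * m.lopt);  // tension-free tendon
  }
  return st;
}

// one physics substep of the muscles: solves CE-SE equilibrium, advances
// lce and activation, returns SE forces
void muscle_substep(const MuscleSet& ms, MuscleStates& st, const vec& q,
                    const vec& S, double dt) {
  for (int i = 0; i < ms.n(); ++i) {
    const MTU& m = ms.mus[i];
    int base = 6 + 4 * m.leg;
    vec qleg = q.subvec(base, base + 3);
    double lm = mtu_length(m, qleg);
    MtuForces f = mtu_equilibrium(m, st.lce(i), st.act(i), lm);
    st.vce(i) = f.vce;
    st.Fse(i) = f.Fse;
    st.lce(i) += f.vce * dt;
    double Sc = std::min(std::max(S(i), 0.0), 1.0);
    st.act(i) += dt * (Sc - st.act(i)) / m.tauA;
    if (st.act(i) < 0.0) st.act(i) = 0.0;
    if (st.act(i) > 1.0) st.act(i) = 1.0;
  }
}

// per-swing-leg descending chain state
struct ChainState {
  vec u_prev, udot_f;
  bool first = true;
  void reset(int n) {
    u_prev = zeros(n);
    udot_f = zeros(n);
    first = true;
  }
};

struct ChainOut {
  vec S;          // 11 stimulations
  vec tau_des;    // 4 desired swing torques
  vec resid;      // 4 torque residuals of C*F - tau
  vec F, Stil, u; // 11 each
};

// planned joint accelerations -> stimulations via inverse dynamics,
// 7-iteration pseudo-inverse force distribution, inverse muscle model and
// reflex inversion.  The threshold-shift command u encodes the *planned*
// CE length (the reference point of the contracted state), so the spinal
// reflex acts as a length servo around the motor plan.
ChainOut descending_step(Plant& P, const MuscleSet& ms, int leg,
                         const vec& qhat, const vec& qdhat, const vec& acc_des,
                         const vec& lce_hat, const vec& vce_hat,
                         const vec& lce_des, const CtrlParams& C,
                         ChainState& cs) {
  int base = 6 + 4 * leg;
  vec qdd = zeros(14);
  qdd.subvec(base, base + 3) = acc_des;
  vec tau_full = rnea(P, qhat, qdhat, qdd, nullptr, true);
  vec tau_sw = tau_full.subvec(base, base + 3);

  mat Cm = moment_arm_matrix(ms, qhat);
  uvec rows = regspace<uvec>(base, base + 3);
  uvec cols = regspace<uvec>(11 * leg, 11 * leg + 10);
  mat Cblk = Cm(rows, cols);

  vec F = distribute_forces(Cblk, tau_sw, C.npinv);
  vec resid = Cblk * F - tau_sw;

  int n = 11;
  vec Stil(n), u(n), S(n);
  for (int j = 0; j < n; ++j) {
    int gi = 11 * leg + j;
    const MTU& m = ms.mus[gi];
    double fl = fl_curve(m, lce_hat(j));
    double fv = fv_curve(m, vce_hat(j));
    double den = std::max(fl * fv, C.flfv_floor) * m.Fmax;
    double s = F(j) / den;
    Stil(j) = std::min(std::max(s, 0.0), 1.0);
    u(j) = (Stil(j) + C.h(gi)) / C.Kl(gi) - lce_des(j);
  }
  if (cs.first) {
    cs.u_prev = u;
    cs.udot_f = zeros(n);
    cs.first = false;
  }
  double dtc = C.dtc();
  for (int j = 0; j < n; ++j) {
    double raw = (u(j) - cs.u_prev(j)) / dtc;
    double al = dtc / (C.udot_tau + dtc);
    cs.udot_f(j) += al * (raw - cs.udot_f(j));
    int gi = 11 * leg + j;
    S(j) = stretch_reflex(lce_hat(j), vce_hat(j), u(j), cs.udot_f(j),
                          C.Kl(gi), C.Kv(gi), C.h(gi), C.Smin);
  }
  cs.u_prev = u;
  ChainOut out;
  out.S = S;
  out.tau_des = tau_sw;
  out.resid = resid;
  out.F = F;
  out.Stil = Stil;
  out.u = u;
  return out;
}

// per-joint replanning state for one leg.  Two parallel plans:
//  - the correction plan, recomputed from the measured state estimate each
//    control step; its integrated jerk is the commanded acceleration fed to
//    the inverse dynamics (feedforward torque channel)
//  - the desired-state plan, which advances an internal desired kinematic
//    state toward the goal; the descending threshold command u encodes its
//    CE lengths, so the stretch reflex servoes deviations from the intended
//    trajectory (feedback channel)
// On-plan both coincide and the reflex reproduces the inverted stimulation
// exactly.
struct PlanState {
  mat coeffs;      // 6 x 4, correction plan
  mat dcoeffs;     // 6 x 4, desired-state plan
  vec acc_prev;    // previous commanded acceleration
  vec xd, vd, ad;  // desired kinematic state
  double t_onset;  // movement onset time
  double T;        // movement duration
  bool frozen;
  double t_frozen; // time at freeze
  void start(double t, double Tdur, const vec& acc0) {
    t_onset = t;
    T = Tdur;
    frozen = false;
    t_frozen = 0;
    acc_prev = acc0;
    coeffs = zeros(6, 4);
    dcoeffs = zeros(6, 4);
  }
  // initialize the desired state (movement onset from rest / phase pickup)
  void reset_desired(const vec& x, const vec& v) {
    xd = x;
    vd = v;
    ad = zeros(4);
  }
};

// filtered estimate of the actual joint accelerations (the acceleration
// component of the current-state boundary condition)
struct AccEstimator {
  vec thd_prev, acc_f;
  bool init = false;
  void reset(int n) {
    thd_prev = zeros(n);
    acc_f = zeros(n);
    init = false;
  }
  const vec& step(const vec& thd, double dtc, double tau) {
    if (!init) {
      thd_prev = thd;
      init = true;
    }
    double al = dtc / (tau + dtc);
    acc_f += al * ((thd - thd_prev) / dtc - acc_f);
    thd_prev = thd;
    return acc_f;
  }
};

// replan all 4 joints toward the goal; returns the commanded acceleration
// one control step ahead (integrated jerk of the correction plan), capped
// at acc_max, and advances the desired state along its own plan.  pos_des
// receives the desired positions a short preview ahead (threshold command
// reference), settling on the goal near the end of the movement.
vec replan_step(PlanState& ps, double t, const vec& th, const vec& thd,
                const vec& acc_est, const vec& goal, const vec& goal_v,
                double dtc, double freeze, double acc_max, double preview,
                vec& pos_des) {
  double Trem = ps.t_onset + ps.T - t;
  vec acc(4);
  pos_des.set_size(4);
  (void)acc_est;
  if (Trem < freeze) {
    if (!ps.frozen) {
      ps.frozen = true;
      ps.t_frozen = t;
    }
    double tf = t - ps.t_frozen + dtc;
    double tend = ps.t_onset + ps.T - ps.t_frozen;
    if (tf >= tend) {
      // past the end of the frozen plan (e.g. waiting for ground contact):
      // hold the goal configuration, never extrapolate the quintic
      acc.zeros();
      pos_des = goal;
      ps.xd = goal;
      ps.vd = goal_v;
      ps.ad.zeros();
      ps.acc_prev = acc;
      return acc;
    }
    double tp = std::min(tf + preview, tend);
    for (int j = 0; j < 4; ++j) {
      double x, v, a;
      minjerk_eval(ps.coeffs.col(j), tf, x, v, a);
      acc(j) = a;
      minjerk_eval(ps.dcoeffs.col(j), tf, x, v, a);
      ps.xd(j) = x;
      ps.vd(j) = v;
      ps.ad(j) = a;
      double xp, vp, ap;
      minjerk_eval(ps.dcoeffs.col(j), tp, xp, vp, ap);
      pos_des(j) = xp;
    }
  } else {
    double tp = std::min(std::max(preview, dtc), Trem);
    for (int j = 0; j < 4; ++j) {
      // correction plan from the measured estimate; boundary acceleration
      // is the previous commanded (capped) acceleration
      ps.coeffs.col(j) = minjerk_coeffs(th(j), thd(j), ps.acc_prev(j), goal(j),
                                        goal_v(j), 0.0, Trem);
      double x, v, a;
      minjerk_eval(ps.coeffs.col(j), dtc, x, v, a);
      acc(j) = a;
      // desired-state plan advances from its own state
      ps.dcoeffs.col(j) = minjerk_coeffs(ps.xd(j), ps.vd(j), ps.ad(j),
                                         goal(j), goal_v(j), 0.0, Trem);
      minjerk_eval(ps.dcoeffs.col(j), dtc, x, v, a);
      ps.xd(j) = x;
      ps.vd(j) = v;
      ps.ad(j) = a;
      double xp, vp, ap;
      minjerk_eval(ps.dcoeffs.col(j), tp, xp, vp, ap);
      pos_des(j) = xp;
    }
  }
  acc = clamp(acc, -acc_max, acc_max);
  ps.acc_prev = acc;
  return acc;
}

// planned CE lengths at a planned leg configuration: the SE carries no
// strain in the inverse muscle model, so lce = lmtu - lslack
vec planned_lce(const MuscleSet& ms, int leg, const vec& qleg_des) {
  vec out(11);
  for (int j = 0; j < 11; ++j) {
    const MTU& m = ms.mus[11 * leg + j];
    out(j) = mtu_length(m, qleg_des) - m.lslack;
  }
  return out;
}

}  // namespace

// ---------------------------------------------------------------------------
// exported primitives (single implementation shared with the simulators)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::vec cpp_rnea(Rcpp::List conf, arma::vec q, arma::vec qd, arma::vec qdd,
                   bool gravity) {
  Plant P = plant_from_list(conf);
  return rnea(P, q, qd, qdd, nullptr, gravity);
}

// [[Rcpp::export]]
arma::mat cpp_mass_matrix(Rcpp::List conf, arma::vec q) {
  Plant P = plant_from_list(conf);
  return mass_matrix(P, q);
}

// [[Rcpp::export]]
arma::vec cpp_fwd_dyn(Rcpp::List conf, arma::vec q, arma::vec qd,
                      arma::vec tau, arma::uvec active1, bool with_contact) {
  Plant P = plant_from_list(conf);
  uvec active = active1 - 1;
  std::vector<SpF> fext(14);
  for (auto& f : fext) {
    f.ang = zeros(3);
    f.lin = zeros(3);
  }
  if (with_contact) {
    fk(P, q);
    SpF fl, fr;
    foot_contact(P, 9, q, qd, fl);
    foot_contact(P, 13, q, qd, fr);
    fext[9] = fl;
    fext[13] = fr;
  }
  vec tau_tot = tau + limit_torques(P, q, qd);
  return fwd_dyn(P, q, qd, tau_tot, &fext, active);
}

// [[Rcpp::export]]
Rcpp::List cpp_contact(Rcpp::List conf, arma::vec q, arma::vec qd) {
  Plant P = plant_from_list(conf);
  fk(P, q);
  SpF fl, fr;
  mat L = foot_contact(P, 9, q, qd, fl);
  mat R = foot_contact(P, 13, q, qd, fr);
  return List::create(Named("left") = L, Named("right") = R,
                      Named("wrench_left") =
                          join_vert(vec(fl.ang), vec(fl.lin)),
                      Named("wrench_right") =
                          join_vert(vec(fr.ang), vec(fr.lin)));
}

// [[Rcpp::export]]
double cpp_energy(Rcpp::List conf, arma::vec q, arma::vec qd) {
  Plant P = plant_from_list(conf);
  mat M = mass_matrix(P, q);
  fk(P, q);
  double E = 0.5 * dot(qd, M * qd);
  for (int i = 0; i < 14; ++i) {
    const Joint& J = P.joints[i];
    if (J.mass <= 0) continue;
    v3 com_w = body_point(P, i, J.com);
    E += J.mass * P.grav * com_w(2);
  }
  return E;
}

// [[Rcpp::export]]
Rcpp::List cpp_fk_points(Rcpp::List conf, arma::vec q) {
  Plant P = plant_from_list(conf);
  fk(P, q);
  mat org(14, 3);
  for (int i = 0; i < 14; ++i) org.row(i) = P.pw[i].t();
  return List::create(Named("origins") = org);
}

// [[Rcpp::export]]
Rcpp::List cpp_mtu_geometry(Rcpp::List mtbl, arma::vec q) {
  MuscleSet ms = muscles_from_list(mtbl);
  vec lm(ms.n());
  for (int i = 0; i < ms.n(); ++i) {
    const MTU& m = ms.mus[i];
    int base = 6 + 4 * m.leg;
    lm(i) = mtu_length(m, q.subvec(base, base + 3));
  }
  mat C = moment_arm_matrix(ms, q);
  return List::create(Named("lmtu") = lm, Named("C") = C);
}

// [[Rcpp::export]]
Rcpp::List cpp_mtu_force(Rcpp::List mtbl, int idx1, double lce, double vce,
                         double act) {
  MuscleSet ms = muscles_from_list(mtbl);
  const MTU& m = ms.mus[idx1 - 1];
  double fl = fl_curve(m, lce);
  double fv = fv_curve(m, vce);
  double Fce = act * m.Fmax * fl * fv;
  double Fpe = fpe_curve(m, lce);
  double Fbe = fbe_curve(m, lce);
  double Fmtu = std::max(Fce + Fpe - Fbe, 0.0);
  return List::create(Named("F_ce") = Fce, Named("F_pe") = Fpe,
                      Named("F_be") = Fbe, Named("F_mtu") = Fmtu,
                      Named("f_l") = fl, Named("f_v") = fv);
}

// [[Rcpp::export]]
Rcpp::List cpp_mtu_equilibrium(Rcpp::List mtbl, int idx1, double lce,
                               double act, double lmtu) {
  MuscleSet ms = muscles_from_list(mtbl);
  MtuForces f = mtu_equilibrium(ms.mus[idx1 - 1], lce, act, lmtu);
  return List::create(Named("F_se") = f.Fse, Named("F_pe") = f.Fpe,
                      Named("F_be") = f.Fbe, Named("v_ce") = f.vce,
                      Named("f_l") = f.fl, Named("f_v") = f.fv);
}

// [[Rcpp::export]]
arma::vec cpp_minjerk_coeffs(arma::vec X0, arma::vec Xtgt, double T) {
  return minjerk_coeffs(X0(0), X0(1), X0(2), Xtgt(0), Xtgt(1), Xtgt(2), T);
}

// [[Rcpp::export]]
arma::mat cpp_minjerk_eval(arma::vec a, arma::vec t) {
  mat out(t.n_elem, 3);
  for (uword i = 0; i < t.n_elem; ++i) {
    double x, v, acc;
    minjerk_eval(a, t(i), x, v, acc);
    out(i, 0) = x;
    out(i, 1) = v;
    out(i, 2) = acc;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_stretch_reflex(double lce, double vce, double u, double udot,
                          double Kl, double Kv, double h, double Smin) {
  return stretch_reflex(lce, vce, u, udot, Kl, Kv, h, Smin);
}

// [[Rcpp::export]]
arma::vec cpp_distribute_forces(arma::mat C, arma::vec tau, int niter) {
  return distribute_forces(C, tau, niter);
}

// ---------------------------------------------------------------------------
// trunk-fixed swing-leg simulation
// ---------------------------------------------------------------------------

// goals: n x 5 matrix [hip_pitch, hip_roll, knee, ankle, duration]
// returns control-rate logs of realized and reference-planned trajectories
// [[Rcpp::export]]
Rcpp::List cpp_simulate_swing(Rcpp::List conf, Rcpp::List mtbl,
                              Rcpp::List ctrl, int leg1, arma::vec q0leg,
                              arma::mat goals, double settle) {
  Plant P = plant_from_list(conf);
  MuscleSet ms = muscles_from_list(mtbl);
  CtrlParams C = ctrl_from_list(ctrl);
  int leg = leg1 - 1;
  int base = 6 + 4 * leg;
  double dtc = C.dtc();

  vec q = zeros(14), qd = zeros(14);
  q(2) = P.trunk_h0 + 1.0;  // trunk fixed high above ground: no contact
  q.subvec(base, base + 3) = q0leg;
  uvec active = regspace<uvec>(base, base + 3);

  MuscleStates mst = init_muscles(ms, q, C.act0);

  // delay lines at control rate
  std::vector<DelayLine> dq(4), dqd(4), dlce(11), dvce(11);
  for (int j = 0; j < 4; ++j) {
    dq[j].init(C.delay_q(base + j), q(base + j));
    dqd[j].init(C.delay_q(base + j), 0.0);
  }
  for (int j = 0; j < 11; ++j) {
    int gi = 11 * leg + j;
    dlce[j].init(C.delay_mus(gi), mst.lce(gi));
    dvce[j].init(C.delay_mus(gi), 0.0);
  }

  ChainState cs;
  cs.reset(11);
  AccEstimator ae;
  ae.reset(4);
  PlanState ps;
  ps.start(0.0, settle > 0 ? settle : goals(0, 4), zeros(4));
  ps.reset_desired(q0leg, zeros(4));

  // schedule: optional settle hold at q0, then the goal sequence
  int ngoal = goals.n_rows;
  int gcur = -1;  // -1 = settle segment
  if (settle <= 0) {
    gcur = 0;
    ps.start(0.0, goals(0, 4), zeros(4));
  }
  double t_next = (settle > 0) ? settle : goals(0, 4);
  vec goal = (gcur < 0) ? q0leg : vec(goals.row(0).subvec(0, 3).t());

  double t_end = (settle > 0 ? settle : 0.0);
  for (int i = 0; i < ngoal; ++i) t_end += goals(i, 4);
  int nsteps = (int)std::round(t_end / dtc);

  // reference plans (from realized state at onset, nominal goal)
  mat refc = zeros(6, 4);
  {
    vec th = q.subvec(base, base + 3);
    for (int j = 0; j < 4; ++j)
      refc.col(j) = minjerk_coeffs(th(j), 0, 0, goal(j), 0, 0,
                                   (gcur < 0) ? (settle > 0 ? settle : 1) :
                                                goals(0, 4));
  }
  double t_ref0 = 0.0;

  mat log_th(nsteps, 4), log_ref(nsteps, 4), log_ank(nsteps, 3),
      log_ankp(nsteps, 3), log_tau(nsteps, 4), log_resid(nsteps, 4),
      log_S(nsteps, 11), log_F(nsteps, 11), log_u(nsteps, 11),
      log_Stil(nsteps, 11), log_act(nsteps, 11), log_Fse(nsteps, 11),
      log_vce(nsteps, 11), log_lce(nsteps, 11);
  vec log_t(nsteps);
  ivec log_seg(nsteps);

  for (int k = 0; k < nsteps; ++k) {
    double t = k * dtc;
    // segment switching
    if (t >= t_next - 0.5 * dtc && gcur < ngoal - 1) {
      gcur += 1;
      goal = goals.row(gcur).subvec(0, 3).t();
      ps.start(t, goals(gcur, 4), ps.acc_prev);
      t_next += goals(gcur, 4);
      // reference plan for the tracking metric: from the realized state at
      // onset (rest-to-rest chains leave negligible onset acceleration)
      vec th = q.subvec(base, base + 3);
      vec thd = qd.subvec(base, base + 3);
      for (int j = 0; j < 4; ++j)
        refc.col(j) = minjerk_coeffs(th(j), thd(j), 0, goal(j), 0,
                                     0, goals(gcur, 4));
      t_ref0 = t;
    }

    // delayed estimates
    vec th_h(4), thd_h(4), lce_h(11), vce_h(11);
    for (int j = 0; j < 4; ++j) {
      th_h(j) = dq[j].step(q(base + j));
      thd_h(j) = dqd[j].step(qd(base + j));
    }
    for (int j = 0; j < 11; ++j) {
      int gi = 11 * leg + j;
      lce_h(j) = dlce[j].step(mst.lce(gi));
      vce_h(j) = dvce[j].step(mst.vce(gi));
    }

    vec acc_est = ae.step(thd_h, dtc, C.acc_tau);
    vec pos_des;
    vec acc = replan_step(ps, t, th_h, thd_h, acc_est, goal, zeros(4), dtc,
                          C.freeze, C.acc_max, C.u_preview, pos_des);
    vec lce_des = planned_lce(ms, leg, pos_des);

    vec qhat = q, qdhat = qd;  // trunk known exactly (fixed)
    qhat.subvec(base, base + 3) = th_h;
    qdhat.subvec(base, base + 3) = thd_h;
    ChainOut co = descending_step(P, ms, leg, qhat, qdhat, acc, lce_h, vce_h,
                                  lce_des, C, cs);

    // physics
    vec S22 = C.Smin * ones(ms.n());
    S22.subvec(11 * leg, 11 * leg + 10) = co.S;
    for (int s = 0; s < C.nsub; ++s) {
      mat Cm = moment_arm_matrix(ms, q);
      vec tau = Cm * mst.Fse + limit_torques(P, q, qd);
      vec qdd = fwd_dyn(P, q, qd, tau, nullptr, active);
      qd += qdd * C.dt;
      q += qd * C.dt;
      muscle_substep(ms, mst, q, S22, C.dt);
    }

    // logs
    log_t(k) = t;
    log_seg(k) = gcur;
    log_th.row(k) = q.subvec(base, base + 3).t();
    double x, v, a;
    vec thref(4);
    for (int j = 0; j < 4; ++j) {
      minjerk_eval(refc.col(j), std::min(t - t_ref0, ps.T), x, v, a);
      thref(j) = x;
    }
    log_ref.row(k) = thref.t();
    fk(P, q);
    log_ank.row(k) = P.pw[base + 3].t();
    vec qp = q;
    qp.subvec(base, base + 3) = thref;
    fk(P, qp);
    log_ankp.row(k) = P.pw[base + 3].t();
    log_tau.row(k) = co.tau_des.t();
    log_resid.row(k) = co.resid.t();
    log_S.row(k) = co.S.t();
    log_F.row(k) = co.F.t();
    log_u.row(k) = co.u.t();
    log_Stil.row(k) = co.Stil.t();
    log_act.row(k) = mst.act.subvec(11 * leg, 11 * leg + 10).t();
    log_Fse.row(k) = mst.Fse.subvec(11 * leg, 11 * leg + 10).t();
    log_vce.row(k) = mst.vce.subvec(11 * leg, 11 * leg + 10).t();
    log_lce.row(k) = mst.lce.subvec(11 * leg, 11 * leg + 10).t();
  }

  return List::create(
      Named("t") = log_t, Named("theta") = log_th, Named("theta_plan") = log_ref,
      Named("ankle") = log_ank, Named("ankle_plan") = log_ankp,
      Named("tau_des") = log_tau, Named("resid") = log_resid,
      Named("S") = log_S, Named("F") = log_F, Named("u") = log_u,
      Named("S_des") = log_Stil, Named("segment") = log_seg,
      Named("act") = log_act, Named("F_se") = log_Fse,
      Named("v_ce") = log_vce, Named("l_ce") = log_lce);
}

// ---------------------------------------------------------------------------
// full walking simulation
// ---------------------------------------------------------------------------

namespace {

struct GaitParams {
  // balance law (per plane)
  double phi0_s, cd_s, cv_s, phi0_f, cd_f, cv_f;
  int delay_bal;       // [control steps]
  double vfilt_tau;
  // swing goals
  vec early_tgt;       // 4
  double T_early, T_early_p, T_late, late_knee, late_ankle;
  int bal_early;       // also apply balance law to early-swing hip targets
  // stance modules
  double g1_vas, g1_sol, g1_gas;
  double ko_phi, ko_vas, ko_bfsh;
  double gp_s, gd_s, th_ref_s;
  double gp_f, gd_f;
  double g4;
  double g_ta, loff_ta, gsup_ta;
  int delay_stance;    // [control steps]
  int delay_trunk;     // [control steps]
  double contact_thresh;
  double load_thresh;     // contralateral load that initiates swing [N]
  double fall_frac;
};

GaitParams gait_from_list(const List& L) {
  GaitParams g;
  g.phi0_s = Rcpp::as<double>(L["phi0_s"]);
  g.cd_s = Rcpp::as<double>(L["cd_s"]);
  g.cv_s = Rcpp::as<double>(L["cv_s"]);
  g.phi0_f = Rcpp::as<double>(L["phi0_f"]);
  g.cd_f = Rcpp::as<double>(L["cd_f"]);
  g.cv_f = Rcpp::as<double>(L["cv_f"]);
  g.delay_bal = Rcpp::as<int>(L["delay_bal"]);
  g.vfilt_tau = Rcpp::as<double>(L["vfilt_tau"]);
  g.early_tgt = Rcpp::as<vec>(L["early_tgt"]);
  g.T_early = Rcpp::as<double>(L["T_early"]);
  g.T_early_p = Rcpp::as<double>(L["T_early_p"]);
  g.T_late = Rcpp::as<double>(L["T_late"]);
  g.late_knee = Rcpp::as<double>(L["late_knee"]);
  g.late_ankle = Rcpp::as<double>(L["late_ankle"]);
  g.bal_early = Rcpp::as<int>(L["bal_early"]);
  g.g1_vas = Rcpp::as<double>(L["g1_vas"]);
  g.g1_sol = Rcpp::as<double>(L["g1_sol"]);
  g.g1_gas = Rcpp::as<double>(L["g1_gas"]);
  g.ko_phi = Rcpp::as<double>(L["ko_phi"]);
  g.ko_vas = Rcpp::as<double>(L["ko_vas"]);
  g.ko_bfsh = Rcpp::as<double>(L["ko_bfsh"]);
  g.gp_s = Rcpp::as<double>(L["gp_s"]);
  g.gd_s = Rcpp::as<double>(L["gd_s"]);
  g.th_ref_s = Rcpp::as<double>(L["th_ref_s"]);
  g.gp_f = Rcpp::as<double>(L["gp_f"]);
  g.gd_f = Rcpp::as<double>(L["gd_f"]);
  g.g4 = Rcpp::as<double>(L["g4"]);
  g.g_ta = Rcpp::as<double>(L["g_ta"]);
  g.loff_ta = Rcpp::as<double>(L["loff_ta"]);
  g.gsup_ta = Rcpp::as<double>(L["gsup_ta"]);
  g.delay_stance = Rcpp::as<int>(L["delay_stance"]);
  g.delay_trunk = Rcpp::as<int>(L["delay_trunk"]);
  g.contact_thresh = Rcpp::as<double>(L["contact_thresh"]);
  g.load_thresh = Rcpp::as<double>(L["load_thresh"]);
  g.fall_frac = Rcpp::as<double>(L["fall_frac"]);
  return g;
}

// muscle roster indices within a leg
enum MusIdx { HFL = 0, GLU, HAM, RF, VAS, BFSH, GAS, SOL, TA, HAB, HAD };

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_simulate_walk(Rcpp::List conf, Rcpp::List mtbl, Rcpp::List ctrl,
                             Rcpp::List gaitL, double duration, arma::vec q0,
                             arma::vec qd0, int swing_first1,
                             Rcpp::List opts) {
  Plant P = plant_from_list(conf);
  MuscleSet ms = muscles_from_list(mtbl);
  CtrlParams C = ctrl_from_list(ctrl);
  GaitParams G = gait_from_list(gaitL);
  double dtc = C.dtc();
  int nsteps = (int)std::round(duration / dtc);
  int nmus = ms.n();

  // options
  bool log_stims = opts.containsElementNamed("log_stims")
                       ? Rcpp::as<bool>(opts["log_stims"])
                       : false;
  int log_every = opts.containsElementNamed("log_every")
                      ? Rcpp::as<int>(opts["log_every"])
                      : 1;
  // perturbation: apply force vector at trunk com starting at the k-th
  // heel-strike, for dur seconds
  bool has_pert = opts.containsElementNamed("perturb");
  int pert_hs = 0;
  vec pert_F = zeros(3);
  double pert_dur = 0;
  if (has_pert) {
    List pl = opts["perturb"];
    pert_hs = Rcpp::as<int>(pl["hs_index"]);
    pert_F = Rcpp::as<vec>(pl["force"]);
    pert_dur = Rcpp::as<double>(pl["dur"]);
  }
  // obstacle: override early-swing targets for one specific swing phase
  bool has_obst = opts.containsElementNamed("obstacle");
  int obst_step = 0;
  vec obst_tgt;
  if (has_obst) {
    List ol = opts["obstacle"];
    obst_step = Rcpp::as<int>(ol["swing_index"]);
    obst_tgt = Rcpp::as<vec>(ol["targets"]);
  }
  // direction: constant hip-roll target offset while heading error is
  // outside tolerance
  bool has_dir = opts.containsElementNamed("direction");
  double dir_target = 0, dir_offset = 0, dir_tol = 0;
  if (has_dir) {
    List dl = opts["direction"];
    dir_target = Rcpp::as<double>(dl["target"]);
    dir_offset = Rcpp::as<double>(dl["offset"]);
    dir_tol = Rcpp::as<double>(dl["tol"]);
  }

  vec q = q0, qd = qd0;
  MuscleStates mst = init_muscles(ms, q, C.act0);

  // FSM: swing_first leg starts in early swing, other in stance
  int swing_first = swing_first1 - 1;
  LegFsm fsm[2];
  fsm[swing_first].phase = EARLY_SWING;
  fsm[swing_first].t_entry = 0;
  fsm[1 - swing_first].phase = STANCE;
  fsm[1 - swing_first].t_entry = 0;

  // delay lines
  std::vector<DelayLine> dq(14), dqd(14), dlce(nmus), dvce(nmus), dF(nmus);
  for (int j = 0; j < 14; ++j) {
    dq[j].init(C.delay_q(j), q(j));
    dqd[j].init(C.delay_q(j), qd(j));
  }
  for (int j = 0; j < nmus; ++j) {
    dlce[j].init(C.delay_mus(j), mst.lce(j));
    dvce[j].init(C.delay_mus(j), 0.0);
    dF[j].init(G.delay_stance, 0.0);
  }
  DelayLine d_ds, d_vs, d_df, d_vf, d_pitch_b, d_roll_b;
  d_ds.init(G.delay_bal, 0);
  d_vs.init(G.delay_bal, 0);
  d_df.init(G.delay_bal, 0);
  d_vf.init(G.delay_bal, 0);
  d_pitch_b.init(G.delay_bal, q(4));
  d_roll_b.init(G.delay_bal, q(5));
  DelayLine d_pitch, d_dpitch, d_roll, d_droll;
  d_pitch.init(G.delay_trunk, q(4));
  d_dpitch.init(G.delay_trunk, qd(4));
  d_roll.init(G.delay_trunk, q(5));
  d_droll.init(G.delay_trunk, qd(5));
  std::vector<DelayLine> d_load(2), d_knee(2), d_dknee(2);
  for (int l = 0; l < 2; ++l) {
    d_load[l].init(G.delay_stance, 0.5);
    d_knee[l].init(G.delay_stance, q(8 + 4 * l));
    d_dknee[l].init(G.delay_stance, 0.0);
  }

  ChainState cs[2];
  cs[0].reset(11);
  cs[1].reset(11);
  AccEstimator ae[2];
  ae[0].reset(4);
  ae[1].reset(4);
  PlanState ps[2];
  vec goal[2], goal_acc0 = zeros(4);
  for (int l = 0; l < 2; ++l) {
    goal[l] = G.early_tgt;
    ps[l].start(0, G.T_early_p, zeros(4));
    ps[l].reset_desired(q.subvec(6 + 4 * l, 9 + 4 * l),
                        qd.subvec(6 + 4 * l, 9 + 4 * l));
  }

  // CoP displacement state
  double cop_x = q(0), cop_y = q(1);
  double ds_f = 0, vs_f = 0, df_f = 0, vf_f = 0, ds_prev = 0, df_prev = 0;
  bool d_init = false;

  // heel-strike bookkeeping
  std::vector<double> hs_t;
  std::vector<int> hs_leg;
  std::vector<double> hs_x, hs_y;
  // limb positions relative to trunk at left heel-strikes (for steadiness)
  std::vector<vec> limb_at_lhs;
  int swing_count[2] = {0, 0};
  swing_count[swing_first] = 1;

  int total_hs = 0;
  // heel-strike detection requires a fresh contact: the swing foot must
  // have unloaded since toe-off before a new ground contact counts
  bool lifted[2] = {false, false};
  double pert_t0 = -1;
  bool fell = false;
  double t_fall = NA_REAL, x_fall = NA_REAL;

  int nlog = nsteps / log_every + 3;
  mat log_q(nlog, 14), log_qd(nlog, 14), log_grf(nlog, 6), log_misc(nlog, 8);
  mat log_S;
  if (log_stims) log_S = zeros(nlog, nmus);
  imat log_phase(nlog, 2);
  vec log_t(nlog);
  int nl = 0;

  SpF fl_c, fr_c;
  fk(P, q);
  mat Lc = foot_contact(P, 9, q, qd, fl_c);
  mat Rc = foot_contact(P, 13, q, qd, fr_c);

  for (int k = 0; k < nsteps; ++k) {
    double t = k * dtc;

    // --- contact state / FSM -------------------------------------------
    double fzL = accu(Lc.col(4)), fzR = accu(Rc.col(4));
    bool contact[2] = {fzL > G.contact_thresh, fzR > G.contact_thresh};

    for (int l = 0; l < 2; ++l) {
      if (fsm[l].phase != STANCE && !contact[l]) lifted[l] = true;
      if (fsm[l].phase == LATE_SWING && contact[l] && lifted[l]) {
        fsm[l].phase = STANCE;
        fsm[l].t_entry = t;
        total_hs += 1;
        fk(P, q);
        v3 fp = P.pw[9 + 4 * l];
        hs_t.push_back(t);
        hs_leg.push_back(l);
        hs_x.push_back(fp(0));
        hs_y.push_back(fp(1));
        if (l == 0) {
          // record limb positions relative to trunk frame origin
          vec rec(12);
          for (int b = 0; b < 4; ++b) {
            int body = (b < 2) ? (8 + 4 * (b % 2)) : (9 + 4 * (b % 2));
            v3 rel = P.pw[body] - P.pw[5];
            rec.subvec(3 * b, 3 * b + 2) = rel;
          }
          limb_at_lhs.push_back(rec);
        }
        if (has_pert && total_hs == pert_hs && pert_t0 < 0) pert_t0 = t;
      } else if (fsm[l].phase == EARLY_SWING &&
                 t - fsm[l].t_entry >= G.T_early) {
        fsm[l].phase = LATE_SWING;
        fsm[l].t_entry = t;
        goal[l] = G.early_tgt;  // hip targets replaced by balance law below
        goal[l](2) = G.late_knee;
        goal[l](3) = G.late_ankle;
        ps[l].start(t, G.T_late, ps[l].acc_prev);
      }
    }

    // trailing leg begins swing once the freshly landed contralateral leg
    // carries a substantial load (double support resolves by weight
    // transfer)
    for (int l = 0; l < 2; ++l) {
      int o = 1 - l;
      if (fsm[l].phase == STANCE && fsm[o].phase == STANCE &&
          fsm[o].t_entry > fsm[l].t_entry) {
        double fz_o = (o == 0) ? fzL : fzR;
        if (fz_o > G.load_thresh) {
          fsm[l].phase = EARLY_SWING;
          fsm[l].t_entry = t;
          lifted[l] = false;
          swing_count[l] += 1;
          cs[l].reset(11);
          vec tgt = G.early_tgt;
          if (has_obst && swing_count[l] == obst_step) tgt = obst_tgt;
          goal[l] = tgt;
          ps[l].start(t, G.T_early_p, zeros(4));
          ps[l].reset_desired(q.subvec(6 + 4 * l, 9 + 4 * l),
                              qd.subvec(6 + 4 * l, 9 + 4 * l));
        }
      }
    }

    // --- balance signals ------------------------------------------------
    fk(P, q);
    v3 trunk_com = body_point(P, 5, P.joints[5].com);
    double fz_tot = fzL + fzR;
    if (fz_tot > 1.0) {
      cop_x = (accu(Lc.col(0) % Lc.col(4)) + accu(Rc.col(0) % Rc.col(4))) /
              fz_tot;
      cop_y = (accu(Lc.col(1) % Lc.col(4)) + accu(Rc.col(1) % Rc.col(4))) /
              fz_tot;
    }
    double yaw = q(3);
    double dx = trunk_com(0) - cop_x, dy = trunk_com(1) - cop_y;
    double d_sag = std::cos(yaw) * dx + std::sin(yaw) * dy;
    double d_frn = -std::sin(yaw) * dx + std::cos(yaw) * dy;
    if (!d_init) {
      ds_prev = d_sag;
      df_prev = d_frn;
      d_init = true;
    }
    double al = dtc / (G.vfilt_tau + dtc);
    vs_f += al * ((d_sag - ds_prev) / dtc - vs_f);
    vf_f += al * ((d_frn - df_prev) / dtc - vf_f);
    ds_prev = d_sag;
    df_prev = d_frn;
    double ds_hat = d_ds.step(d_sag), vs_hat = d_vs.step(vs_f);
    double df_hat = d_df.step(d_frn), vf_hat = d_vf.step(vf_f);
    double pitch_bal = d_pitch_b.step(q(4)), roll_bal = d_roll_b.step(q(5));

    // --- delayed proprioceptive estimates -------------------------------
    vec qhat(14), qdhat(14);
    for (int j = 0; j < 14; ++j) {
      qhat(j) = dq[j].step(q(j));
      qdhat(j) = dqd[j].step(qd(j));
    }
    vec lce_h(nmus), vce_h(nmus), Fn_h(nmus);
    for (int j = 0; j < nmus; ++j) {
      lce_h(j) = dlce[j].step(mst.lce(j));
      vce_h(j) = dvce[j].step(mst.vce(j));
      Fn_h(j) = dF[j].step(mst.Fse(j) / ms.mus[j].Fmax);
    }
    double pitch_h = d_pitch.step(q(4)), dpitch_h = d_dpitch.step(qd(4));
    double roll_h = d_roll.step(q(5)), droll_h = d_droll.step(qd(5));
    double load_h[2], knee_h[2], dknee_h[2];
    double denom_load = std::max(fzL + fzR, 1.0);
    for (int l = 0; l < 2; ++l) {
      load_h[l] = d_load[l].step((l == 0 ? fzL : fzR) / denom_load);
      knee_h[l] = d_knee[l].step(q(8 + 4 * l));
      dknee_h[l] = d_dknee[l].step(qd(8 + 4 * l));
    }

    // --- per-leg control -------------------------------------------------
    for (int l = 0; l < 2; ++l) {
      ae[l].step(qdhat.subvec(6 + 4 * l, 9 + 4 * l), dtc, C.acc_tau);
    }
    vec S22 = C.Smin * ones(nmus);
    vec tau_sw_hip[2];
    tau_sw_hip[0] = zeros(1);
    tau_sw_hip[1] = zeros(1);

    // swing legs first (stance module 4 uses the swing hip torque)
    for (int l = 0; l < 2; ++l) {
      if (fsm[l].phase == STANCE) continue;
      double sside = (l == 0) ? 1.0 : -1.0;
      // balance-law hip targets
      double d_out = sside * df_hat, v_out = sside * vf_hat;
      double phi_thigh_s = G.phi0_s + G.cd_s * ds_hat + G.cv_s * vs_hat;
      double phi_thigh_f = G.phi0_f + G.cd_f * d_out + G.cv_f * v_out;
      double tgt_hip_s = phi_thigh_s + pitch_bal;
      double tgt_hip_f = sside * roll_bal - phi_thigh_f;
      vec geff = goal[l];
      if (fsm[l].phase == LATE_SWING || G.bal_early) {
        geff(0) = tgt_hip_s;
        geff(1) = tgt_hip_f;
      }
      if (has_dir) {
        double err = dir_target - q(3);
        if (std::fabs(err) > dir_tol)
          geff(1) += (err > 0 ? 1.0 : -1.0) * dir_offset;
      }
      int base = 6 + 4 * l;
      // goals stay within the joint range of motion
      for (int j = 0; j < 4; ++j) {
        geff(j) = std::min(std::max(geff(j), P.lim_lo(base + j)),
                           P.lim_hi(base + j));
      }
      vec th_h = qhat.subvec(base, base + 3);
      vec thd_h = qdhat.subvec(base, base + 3);
      vec pos_des;
      vec acc = replan_step(ps[l], t, th_h, thd_h, ae[l].acc_f, geff,
                            zeros(4), dtc, C.freeze, C.acc_max, C.u_preview, pos_des);
      vec lce_des = planned_lce(ms, l, pos_des);
      vec lch = lce_h.subvec(11 * l, 11 * l + 10);
      vec vch = vce_h.subvec(11 * l, 11 * l + 10);
      ChainOut co = descending_step(P, ms, l, qhat, qdhat, acc, lch, vch,
                                    lce_des, C, cs[l]);
      S22.subvec(11 * l, 11 * l + 10) = co.S;
      tau_sw_hip[l](0) = co.tau_des(0);
    }

    // stance legs
    for (int l = 0; l < 2; ++l) {
      if (fsm[l].phase != STANCE) continue;
      double sside = (l == 0) ? 1.0 : -1.0;
      int mb = 11 * l;
      StanceGains sg;
      sg.g1_vas = G.g1_vas; sg.g1_sol = G.g1_sol; sg.g1_gas = G.g1_gas;
      sg.ko_phi = G.ko_phi; sg.ko_vas = G.ko_vas; sg.ko_bfsh = G.ko_bfsh;
      sg.gp_s = G.gp_s; sg.gd_s = G.gd_s; sg.th_ref_s = G.th_ref_s;
      sg.gp_f = G.gp_f; sg.gd_f = G.gd_f; sg.g4 = G.g4;
      sg.g_ta = G.g_ta; sg.loff_ta = G.loff_ta; sg.gsup_ta = G.gsup_ta;
      sg.Smin = C.Smin;
      StanceSignals ss;
      ss.Fn_vas = Fn_h(mb + VAS);
      ss.Fn_sol = Fn_h(mb + SOL);
      ss.Fn_gas = Fn_h(mb + GAS);
      ss.knee = knee_h[l];
      ss.dknee = dknee_h[l];
      ss.pitch = pitch_h;
      ss.dpitch = dpitch_h;
      ss.roll_rel = sside * roll_h;
      ss.droll_rel = sside * droll_h;
      ss.load = load_h[l];
      int o = 1 - l;
      ss.tau_sw_hip = (fsm[o].phase != STANCE) ? tau_sw_hip[o](0) : 0.0;
      ss.lce_ta_norm = lce_h(mb + TA) / ms.mus[mb + TA].lopt;
      S22.subvec(mb, mb + 10) = stance_module_stims(sg, ss);
    }

    // --- physics ---------------------------------------------------------
    uvec active = regspace<uvec>(0, 13);
    bool pert_on = pert_t0 >= 0 && t >= pert_t0 && t < pert_t0 + pert_dur;
    for (int s = 0; s < C.nsub; ++s) {
      fk(P, q);
      std::vector<SpF> fext(14);
      for (auto& f : fext) {
        f.ang = zeros(3);
        f.lin = zeros(3);
      }
      Lc = foot_contact(P, 9, q, qd, fl_c);
      Rc = foot_contact(P, 13, q, qd, fr_c);
      fext[9] = fl_c;
      fext[13] = fr_c;
      if (pert_on) {
        v3 com_w = body_point(P, 5, P.joints[5].com);
        fext[5].lin += pert_F;
        fext[5].ang += cross(com_w - P.pw[5], pert_F);
      }
      mat Cm = moment_arm_matrix(ms, q);
      vec tau = Cm * mst.Fse + limit_torques(P, q, qd);
      vec qdd = fwd_dyn(P, q, qd, tau, &fext, active);
      qd += qdd * C.dt;
      q += qd * C.dt;
      muscle_substep(ms, mst, q, S22, C.dt);
    }

    // --- fall detection / logging ---------------------------------------
    if (q(2) < G.fall_frac * P.trunk_h0 || !q.is_finite() ||
        std::fabs(qd(0)) > 20) {
      fell = true;
      t_fall = t;
      x_fall = q(0);
    }
    if (k % log_every == 0 || fell) {
      log_t(nl) = t;
      log_q.row(nl) = q.t();
      log_qd.row(nl) = qd.t();
      log_grf(nl, 0) = accu(Lc.col(5));
      log_grf(nl, 1) = accu(Lc.col(6));
      log_grf(nl, 2) = fzL;
      log_grf(nl, 3) = accu(Rc.col(5));
      log_grf(nl, 4) = accu(Rc.col(6));
      log_grf(nl, 5) = fzR;
      log_phase(nl, 0) = fsm[0].phase;
      log_phase(nl, 1) = fsm[1].phase;
      log_misc(nl, 0) = cop_x;
      log_misc(nl, 1) = cop_y;
      log_misc(nl, 2) = d_sag;
      log_misc(nl, 3) = d_frn;
      log_misc(nl, 4) = trunk_com(0);
      log_misc(nl, 5) = trunk_com(1);
      log_misc(nl, 6) = trunk_com(2);
      log_misc(nl, 7) = fz_tot;
      if (log_stims) log_S.row(nl) = S22.t();
      nl += 1;
    }
    if (fell) break;
  }

  // steadiness measure: summed limb-position changes across the last three
  // left heel-strikes
  double d_steady = NA_REAL;
  int nlhs = (int)limb_at_lhs.size();
  if (nlhs >= 4) {
    d_steady = 0;
    for (int j = nlhs - 3; j < nlhs; ++j) {
      for (int b = 0; b < 4; ++b) {
        vec d = limb_at_lhs[j].subvec(3 * b, 3 * b + 2) -
                limb_at_lhs[j - 1].subvec(3 * b, 3 * b + 2);
        d_steady += norm(d, 2);
      }
    }
  }

  mat hs(hs_t.size(), 4);
  for (size_t i = 0; i < hs_t.size(); ++i) {
    hs(i, 0) = hs_t[i];
    hs(i, 1) = hs_leg[i];
    hs(i, 2) = hs_x[i];
    hs(i, 3) = hs_y[i];
  }

  List out = List::create(
      Named("t") = log_t.head(nl), Named("q") = log_q.head_rows(nl),
      Named("qd") = log_qd.head_rows(nl), Named("grf") = log_grf.head_rows(nl),
      Named("phase") = log_phase.head_rows(nl),
      Named("misc") = log_misc.head_rows(nl), Named("heel_strikes") = hs,
      Named("fell") = fell, Named("t_fall") = t_fall,
      Named("x_fall") = x_fall, Named("d_steady") = d_steady);
  if (log_stims) out["S"] = log_S.head_rows(nl);
  return out;
}

// ---------------------------------------------------------------------------
// additional exported primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::vec cpp_stance_stims(Rcpp::List gains, Rcpp::List signals) {
  StanceGains g;
  g.g1_vas = Rcpp::as<double>(gains["g1_vas"]);
  g.g1_sol = Rcpp::as<double>(gains["g1_sol"]);
  g.g1_gas = Rcpp::as<double>(gains["g1_gas"]);
  g.ko_phi = Rcpp::as<double>(gains["ko_phi"]);
  g.ko_vas = Rcpp::as<double>(gains["ko_vas"]);
  g.ko_bfsh = Rcpp::as<double>(gains["ko_bfsh"]);
  g.gp_s = Rcpp::as<double>(gains["gp_s"]);
  g.gd_s = Rcpp::as<double>(gains["gd_s"]);
  g.th_ref_s = Rcpp::as<double>(gains["th_ref_s"]);
  g.gp_f = Rcpp::as<double>(gains["gp_f"]);
  g.gd_f = Rcpp::as<double>(gains["gd_f"]);
  g.g4 = Rcpp::as<double>(gains["g4"]);
  g.g_ta = Rcpp::as<double>(gains["g_ta"]);
  g.loff_ta = Rcpp::as<double>(gains["loff_ta"]);
  g.gsup_ta = Rcpp::as<double>(gains["gsup_ta"]);
  g.Smin = Rcpp::as<double>(gains["Smin"]);
  StanceSignals s;
  s.Fn_vas = Rcpp::as<double>(signals["Fn_vas"]);
  s.Fn_sol = Rcpp::as<double>(signals["Fn_sol"]);
  s.Fn_gas = Rcpp::as<double>(signals["Fn_gas"]);
  s.knee = Rcpp::as<double>(signals["knee"]);
  s.dknee = Rcpp::as<double>(signals["dknee"]);
  s.pitch = Rcpp::as<double>(signals["pitch"]);
  s.dpitch = Rcpp::as<double>(signals["dpitch"]);
  s.roll_rel = Rcpp::as<double>(signals["roll_rel"]);
  s.droll_rel = Rcpp::as<double>(signals["droll_rel"]);
  s.load = Rcpp::as<double>(signals["load"]);
  s.tau_sw_hip = Rcpp::as<double>(signals["tau_sw_hip"]);
  s.lce_ta_norm = Rcpp::as<double>(signals["lce_ta_norm"]);
  return stance_module_stims(g, s);
}

// [[Rcpp::export]]
Rcpp::List cpp_fsm_update(int phase, double t_entry, double t,
                          bool ipsi_contact, bool contra_contact,
                          double t_early) {
  LegFsm f;
  f.phase = (Phase)phase;
  f.t_entry = t_entry;
  bool tr = f.update(t, ipsi_contact, contra_contact, t_early);
  return Rcpp::List::create(Rcpp::Named("phase") = (int)f.phase,
                            Rcpp::Named("t_entry") = f.t_entry,
                            Rcpp::Named("transitioned") = tr);
}

// [[Rcpp::export]]
double cpp_balance_target(double phi0, double cd, double cv, double d_hat,
                          double v_hat, double phi_trunk_hat) {
  return balance_target(phi0, cd, cv, d_hat, v_hat, phi_trunk_hat);
}

// [[Rcpp::export]]
arma::mat cpp_muscle_curves(Rcpp::List mtbl, arma::vec lce, arma::vec vce) {
  MuscleSet ms = muscles_from_list(mtbl);
  arma::mat out(ms.n(), 2);
  for (int i = 0; i < ms.n(); ++i) {
    out(i, 0) = fl_curve(ms.mus[i], lce(i));
    out(i, 1) = fv_curve(ms.mus[i], vce(i));
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_delay_signal(arma::vec x, int steps) {
  DelayLine d;
  d.init(steps, x(0));
  arma::vec out(x.n_elem);
  for (arma::uword i = 0; i < x.n_elem; ++i) out(i) = d.step(x(i));
  return out;
}
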