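#ifndef FLEXGAIT_MUSCLE_H
#define FLEXGAIT_MUSCLE_H

#include <RcppArmadillo.h>

// 22 Hill-type muscle-tendon units (11 per leg).
//
// Each MTU: contractile element (CE) with force-length and force-velocity
// relations, series elastic element (SE, tendon), parallel element (PE,
// resists over-stretch) and buffer element (BE, resists over-compression).
// F_ce = A * Fmax * f_l(l_ce) * f_v(v_ce);  F_mtu = F_se = F_ce + F_pe - F_be.
// Forward simulation treats l_ce as a state and solves the CE-SE force
// equilibrium for v_ce each step (inverting f_v).
//
// Geometry: MTU length is an explicit function of the spanned joint angles
// with constant or cosine-saturating moment arms; the moment-arm matrix is
// the exact negative derivative of MTU length (virtual-work consistent).

namespace flexgait {

struct MTU {
  int leg;             // 0 left, 1 right
  double Fmax;         // max isometric force [N]
  double lopt;         // optimal CE length [m]
  double lslack;       // SE slack length [m]
  double vmax;         // max shortening velocity [m/s]
  double w;            // f_l width (fraction of lopt)
  double fvN;          // eccentric force plateau (f_v max)
  double fvK;          // f_v curvature
  double epsref;       // SE strain at Fmax
  double tauA;         // activation time constant [s]
  int ndof;            // spanned leg DoFs (1 or 2)
  int dof[2];          // leg-local DoF index: 0 hip pitch, 1 hip roll,
                       // 2 knee, 3 ankle
  double r0[2];        // peak moment arm [m]
  double thmax[2];     // angle of peak arm for cos saturation; NaN = constant
  double thref[2];     // reference angle where this attachment adds no length
  double sgn[2];       // +1: positive force drives DoF positive
};

struct MuscleSet {
  std::vector<MTU> mus;
  int n() const { return (int)mus.size(); }
};

// Hill curves
double fl_curve(const MTU& m, double lce);
double fv_curve(const MTU& m, double vce);
double fv_inverse(const MTU& m, double fv);
double fse_curve(const MTU& m, double lse);
double fpe_curve(const MTU& m, double lce);
double fbe_curve(const MTU& m, double lce);

// geometry for one muscle given the 4 leg-local joint angles
double mtu_length(const MTU& m, const arma::vec& qleg);
void mtu_arms(const MTU& m, const arma::vec& qleg, double* arm_out);
double mtu_velocity(const MTU& m, const arma::vec& qleg, const arma::vec& qdleg);

// CE velocity from CE-SE force equilibrium; also returns forces
struct MtuForces {
  double Fse, Fce, Fpe, Fbe, vce, fl, fv;
};
MtuForces mtu_equilibrium(const MTU& m, double lce, double act, double lmtu);

// full-model moment arm matrix (14 x n) at configuration q (global coords)
arma::mat moment_arm_matrix(const MuscleSet& ms, const arma::vec& q);

MuscleSet muscles_from_list(const Rcpp::List& tbl);

}  // namespace flexgait

#endif
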