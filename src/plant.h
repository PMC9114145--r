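#ifndef FLEXGAIT_PLANT_H
#define FLEXGAIT_PLANT_H

#include <RcppArmadillo.h>

// Articulated rigid-body model of the 7-segment biped.
//
// 14 generalized coordinates, ordered [trunk 6; left leg 4; right leg 4]:
//   0..2  trunk translation x (forward), y (left), z (up)
//   3..5  trunk yaw (z), pitch (y, forward lean positive), roll (x)
//   6..9  left  hip pitch (flexion +), hip roll (adduction +), knee (flexion +),
//         ankle (dorsiflexion +)
//   10..13 right leg, same order
//
// Dynamics via recursive Newton-Euler (inverse dynamics) in Plucker/spatial
// coordinates; mass matrix assembled column-wise from unit-acceleration RNEA
// sweeps, so forward and inverse dynamics are algebraically consistent.

namespace flexgait {

typedef arma::vec3 v3;
typedef arma::mat33 m3;

struct SpV { v3 ang; v3 lin; };   // spatial motion vector
struct SpF { v3 ang; v3 lin; };   // spatial force vector (moment; force)

inline v3 cross(const v3& a, const v3& b) { return arma::cross(a, b); }

struct Joint {
  int parent;      // parent joint index, -1 for world
  int type;        // 0 prismatic, 1 revolute
  v3 axis;         // joint axis in local (child) frame
  v3 ptree;        // joint position in parent body frame
  // body attached distal to this joint
  double mass;
  v3 com;          // center of mass in body frame
  m3 Icom;         // rotational inertia about com, body frame
};

struct ContactParams {
  double kn;       // normal stiffness [N/m]
  double cn;       // Hunt-Crossley damping factor [s/m]
  double mu;       // friction coefficient
  double vreg;     // friction regularization velocity [m/s]
};

struct Plant {
  static const int NQ = 14;
  Joint joints[NQ];
  double grav;                 // gravitational acceleration (positive number)
  // soft range-of-motion limits for the 8 internal DoFs (indices 6..13)
  arma::vec lim_lo, lim_hi;    // length NQ (trunk entries unused)
  double lim_k, lim_d;         // limit stiffness [N*m/rad] and damping
  // foot contact geometry: 4 points per foot in foot frame
  arma::mat cpts;              // 4 x 3
  ContactParams cp;
  double trunk_h0;             // standing height of trunk frame origin (pelvis)

  // kinematics cache (filled by fk())
  m3 Rw[NQ];   // body-to-world rotation
  v3 pw[NQ];   // body origin in world
};

struct KinState {
  arma::vec q, qd;   // length 14
};

// forward kinematics: fill Rw, pw
void fk(Plant& P, const arma::vec& q);

// world-frame velocity of a body-frame point (requires fk + body spatial vel)
// full RNEA: returns tau = M qdd + C + G - J^T f_ext
// f_ext: per-body spatial forces expressed in WORLD frame about body origin
arma::vec rnea(Plant& P, const arma::vec& q, const arma::vec& qd,
               const arma::vec& qdd, const std::vector<SpF>* fext_world,
               bool gravity);

arma::mat mass_matrix(Plant& P, const arma::vec& q);

// forward dynamics on an active-DoF subset; inactive DoFs get qdd = 0.
arma::vec fwd_dyn(Plant& P, const arma::vec& q, const arma::vec& qd,
                  const arma::vec& tau, const std::vector<SpF>* fext_world,
                  const arma::uvec& active);

// contact forces for one foot; returns per-point rows
// [px py pz pen fz fx fy] (world frame) and accumulates a world-frame
// spatial force about the foot body origin into fout.
arma::mat foot_contact(Plant& P, int foot_body, const arma::vec& q,
                       const arma::vec& qd, SpF& fout);

// soft joint-limit torques for internal DoFs
arma::vec limit_torques(const Plant& P, const arma::vec& q, const arma::vec& qd);

// world position / velocity of a point fixed in a body
v3 body_point(const Plant& P, int body, const v3& plocal);
v3 body_point_vel(Plant& P, int body, const arma::vec& q, const arma::vec& qd,
                  const v3& plocal);

Plant plant_from_list(const Rcpp::List& conf);

}  // namespace flexgait

#endif
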