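#' Default anthropometric body model
#'
#' Seven-segment biped (trunk, two thighs, shanks and feet) representing a
#' person of 1.80 m height and 80 kg mass, with 14 generalized coordinates:
#' six free-body trunk DoFs (translation x/y/z, then yaw, pitch, roll) and
#' four internal DoFs per leg (hip pitch, hip roll, knee, ankle).  Hip and
#' knee flexion and ankle dorsiflexion are positive; hip adduction is
#' positive toward the midline.  All units SI, angles in radians.
#'
#' Each foot carries four contact points, two at the heel (5 cm lateral
#' spacing) and two at the forefoot (10 cm spacing).  Ground contact is a
#' compliant normal force \code{kn * pen * (1 + cn * pen_rate)} with
#' regularized Coulomb friction, parameterized to emulate a hard surface
#' with sub-5 mm penetration under body weight.  Soft exponential-free
#' spring-damper torques engage beyond the joint range of motion.
#'
#' @param total_mass total body mass in kg
#' @param gravity gravitational acceleration in m/s^2
#' @return an object of class \code{fg_body}: a named list of segment,
#'   contact and joint-limit parameters consumed by the dynamics core.
#' @export
default_body <- function(total_mass = 80, gravity = 9.81) {
  s <- total_mass / 80
  body <- list(
    gravity = gravity,
    # trunk lumps head and arms; frame origin at the pelvis center
    trunk = list(mass = 53.5 * s, com = c(0, 0, 0.35),
                 I = c(3.9, 3.9, 0.6) * s),
    hip_width = 0.18,
    thigh = list(mass = 8.5 * s, length = 0.46, com_offset = 0.20,
                 I = c(0.15, 0.15, 0.02) * s),
    shank = list(mass = 3.5 * s, length = 0.46, com_offset = 0.20,
                 I = c(0.055, 0.055, 0.005) * s),
    foot = list(mass = 1.25 * s, com = c(0.05, 0, -0.05),
                I = c(0.002, 0.007, 0.007) * s),
    limits = list(lo = c(-0.35, -0.35, 0.0, -0.8),
                  hi = c(1.75, 0.35, 2.62, 0.6),
                  k = 300, d = 30),
    contact = list(
      points = rbind(c(-0.07,  0.025, -0.08),
                     c(-0.07, -0.025, -0.08),
                     c( 0.13,  0.050, -0.08),
                     c( 0.13, -0.050, -0.08)),
      kn = 60000, cn = 3, mu = 0.9, vreg = 0.05),
    trunk_h0 = 1.0
  )
  class(body) <- "fg_body"
  body
}

#' Body state
#'
#' @param theta 14-vector of generalized coordinates (rad / m)
#' @param theta_dot 14-vector of generalized velocities
#' @export
body_state <- function(theta, theta_dot = rep(0, 14)) {
  stopifnot(length(theta) == 14, length(theta_dot) == 14,
            all(is.finite(theta)), all(is.finite(theta_dot)))
  structure(list(theta = as.numeric(theta), theta_dot = as.numeric(theta_dot)),
            class = "fg_state")
}

#' Forward dynamics
#'
#' Solves the equation of motion M(theta) theta_dd + C(theta, theta_dot) +
#' G(theta) + T_ext = tau for the joint accelerations, optionally including
#' ground contact wrenches.  Torques on the six un-actuated free-body trunk
#' DoFs must be zero when all DoFs are active.
#'
#' @param body an \code{fg_body}
#' @param state an \code{fg_state} (or list with theta, theta_dot)
#' @param torques 14-vector of joint torques in N m
#' @param active indices of active DoFs (inactive ones are held at zero
#'   acceleration, e.g. to fix the trunk in space)
#' @param contact include compliant ground contact forces
#' @return 14-vector of generalized accelerations
#' @export
forward_dynamics <- function(body, state, torques = rep(0, 14),
                             active = 1:14, contact = FALSE) {
  stopifnot(all(is.finite(state$theta)), all(is.finite(state$theta_dot)),
            all(is.finite(torques)))
  M <- cpp_mass_matrix(unclass(body), state$theta)
  Ma <- M[active, active, drop = FALSE]
  if (rcond(Ma) < 1e-12) {
    stop("mass matrix is numerically singular: check segment parameters")
  }
  drop(cpp_fwd_dyn(unclass(body), state$theta, state$theta_dot, torques,
                   as.integer(active), contact))
}

#' Inverse dynamics
#'
#' Returns M(theta) theta_dd + C(theta, theta_dot) + G(theta).  Ground
#' contact forces are deliberately not included: the controller's internal
#' model treats the swing leg as contact-free.
#'
#' @param body an \code{fg_body}
#' @param theta,theta_dot,theta_ddot 14-vectors
#' @return 14-vector of joint torques in N m
#' @export
inverse_dynamics <- function(body, theta, theta_dot, theta_ddot) {
  stopifnot(all(is.finite(theta)), all(is.finite(theta_dot)),
            all(is.finite(theta_ddot)))
  drop(cpp_rnea(unclass(body), theta, theta_dot, theta_ddot, TRUE))
}

#' Ground contact forces
#'
#' Per-point compliant normal forces and regularized Coulomb friction for
#' the four contact points under each foot.
#'
#' @param body an \code{fg_body}
#' @param state an \code{fg_state}
#' @return a data.frame with one row per contact point: foot side, world
#'   position, penetration depth, normal and tangential force components.
#' @export
contact_forces <- function(body, state) {
  cc <- cpp_contact(unclass(body), state$theta, state$theta_dot)
  pts <- rbind(cc$left, cc$right)
  out <- data.frame(
    side = rep(c("left", "right"), each = nrow(cc$left)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    penetration = pts[, 4],
    f_normal = pts[, 5], f_tan_x = pts[, 6], f_tan_y = pts[, 7]
  )
  out
}

#' Advance the passive skeleton one (or more) integration steps
#'
#' Fixed-step semi-implicit Euler of the rigid-body dynamics under gravity,
#' joint-limit torques and (optionally) ground contact; no muscles.  Mainly
#' used for testing conservation properties and contact behavior.
#'
#' @param body an \code{fg_body}
#' @param state an \code{fg_state}
#' @param torques applied joint torques (held constant)
#' @param dt integration step in s
#' @param n number of steps
#' @param active active DoF indices
#' @param contact include ground contact
#' @return the new \code{fg_state}
#' @export
integrate_step <- function(body, state, torques = rep(0, 14), dt = 1e-4,
                           n = 1, active = 1:14, contact = FALSE) {
  stopifnot(dt > 0)
  q <- state$theta
  qd <- state$theta_dot
  conf <- unclass(body)
  for (k in seq_len(n)) {
    qdd <- cpp_fwd_dyn(conf, q, qd, torques, as.integer(active), contact)
    qd <- qd + qdd * dt
    q <- q + qd * dt
    if (any(abs(qd) > 200)) {
      stop("simulation blow-up: generalized velocity exceeded bound")
    }
  }
  body_state(q, qd)
}

#' Total mechanical energy of the skeleton
#' @param body an \code{fg_body}
#' @param state an \code{fg_state}
#' @export
body_energy <- function(body, state) {
  cpp_energy(unclass(body), state$theta, state$theta_dot)
}

#' Joint-center world positions
#'
#' Forward kinematics; row i is the origin of body i in the fixed coordinate
#' ordering (trunk chain 1:6, left hip/thigh/shank/foot 7:10, right 11:14).
#' The shank origin is the knee joint center and the foot origin the ankle.
#'
#' @param body an \code{fg_body}
#' @param theta 14-vector of generalized coordinates
#' @export
joint_centers <- function(body, theta) {
  cpp_fk_points(unclass(body), theta)$origins
}

#' Standing configuration resting on the ground
#'
#' Upright posture with both feet flat; the vertical coordinate is preloaded
#' so the contact springs carry the body weight.
#'
#' @param body an \code{fg_body}
#' @param lean initial forward trunk pitch in rad
#' @export
standing_state <- function(body, lean = 0) {
  w <- (body$trunk$mass + 2 * (body$thigh$mass + body$shank$mass +
                                 body$foot$mass)) * body$gravity
  q <- rep(0, 14)
  q[3] <- body$trunk_h0 - w / (8 * body$contact$kn)
  q[5] <- lean
  body_state(q)
}
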