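#' Behavioral finite state machine update
#'
#' Each leg cycles through stance -> early swing -> late swing -> stance.
#' Early swing starts when ground contact of the contralateral leg is
#' detected; the transition to late swing occurs after a fixed time of
#' 0.3 s; late swing ends at ipsilateral ground contact.
#'
#' @param phase current phase: "early_swing", "late_swing" or "stance"
#' @param t_entry time the current phase was entered, s
#' @param t current time, s
#' @param ipsi_contact,contra_contact loaded ground contact of this / the
#'   other leg (normal force above threshold)
#' @param t_early early-swing duration, s
#' @return list with the new \code{phase}, \code{t_entry} and whether a
#'   \code{transitioned} occurred
#' @export
fsm_update <- function(phase, t_entry, t, ipsi_contact, contra_contact,
                       t_early = 0.3) {
  codes <- c(early_swing = 0L, late_swing = 1L, stance = 2L)
  stopifnot(phase %in% names(codes))
  out <- cpp_fsm_update(codes[[phase]], t_entry, t, ipsi_contact,
                        contra_contact, t_early)
  list(phase = names(codes)[out$phase + 1L], t_entry = out$t_entry,
       transitioned = out$transitioned)
}

#' Balance-law hip target
#'
#' Foot-placement balance: the desired thigh orientation in space is
#' \code{phi_thigh = phi0 + c_d d + c_v v} from the (delayed) horizontal
#' displacement d between center of pressure and trunk center and its rate
#' v; the hip target angle follows by subtracting the delayed trunk
#' orientation.  Applied independently in the sagittal and frontal plane.
#'
#' @param d_hat,v_hat delayed CoP-to-trunk displacement (m) and rate (m/s)
#' @param phi_trunk_hat delayed trunk orientation in the same plane, rad
#' @param phi0 constant thigh-angle offset, rad
#' @param c_d,c_v displacement and velocity feedback gains
#' @return target hip angle, rad
#' @export
balance_targets <- function(d_hat, v_hat, phi_trunk_hat, phi0, c_d, c_v) {
  cpp_balance_target(phi0, c_d, c_v, d_hat, v_hat, phi_trunk_hat)
}

#' Minimum-jerk quintic coefficients
#'
#' The unique 5th-order polynomial satisfying position, velocity and
#' acceleration boundary conditions at t = 0 and t = T (the minimum-jerk
#' trajectory between the two states).
#'
#' @param X0 initial state c(x, xd, xdd)
#' @param Xtgt goal state c(x, xd, xdd)
#' @param T movement duration, s (> 0)
#' @return coefficients a0..a5
#' @export
minjerk_coeffs <- function(X0, Xtgt, T) {
  if (T <= 0) stop("movement duration must be positive")
  drop(cpp_minjerk_coeffs(as.numeric(X0), as.numeric(Xtgt), T))
}

#' Evaluate a quintic motor plan
#'
#' @param coeffs coefficients a0..a5 from \code{\link{minjerk_coeffs}}
#' @param t evaluation times
#' @return matrix with columns x, xd, xdd
#' @export
minjerk_eval <- function(coeffs, t) {
  out <- cpp_minjerk_eval(coeffs, as.numeric(t))
  colnames(out) <- c("x", "xd", "xdd")
  out
}

#' Online replanning: desired acceleration toward the goal
#'
#' Recomputes the minimum-jerk plan from the current state estimate to the
#' goal over the remaining movement time and returns the plan's
#' acceleration one control step ahead (the integrated jerk).  For
#' remaining times below the freeze window (0.03 s) the plan is no longer
#' updated and the previous coefficients are evaluated instead.
#'
#' @param current state estimate c(x, xd, xdd)
#' @param goal goal state c(x, xd, xdd)
#' @param t_remaining remaining movement time, s
#' @param dt control step, s
#' @param freeze freeze window, s
#' @param frozen_coeffs previous plan coefficients, used when frozen
#' @param t_since_freeze time since the plan was frozen, s
#' @return list with \code{acc} (commanded acceleration), \code{coeffs}
#'   and \code{frozen}
#' @export
replan_acceleration <- function(current, goal, t_remaining, dt = 1e-3,
                                freeze = 0.03, frozen_coeffs = NULL,
                                t_since_freeze = 0) {
  if (t_remaining < freeze) {
    if (is.null(frozen_coeffs)) {
      stop("plan frozen but no previous coefficients supplied")
    }
    s <- minjerk_eval(frozen_coeffs, t_since_freeze + dt)
    return(list(acc = s[1, "xdd"], coeffs = frozen_coeffs, frozen = TRUE))
  }
  co <- minjerk_coeffs(current, goal, t_remaining)
  s <- minjerk_eval(co, dt)
  list(acc = s[1, "xdd"], coeffs = co, frozen = FALSE)
}

#' Obstacle-avoidance swing targets
#'
#' Linear retargeting of the early-swing goal configuration for stepping
#' over (sagittal) or around (medial-lateral) an obstacle:
#' \code{theta_i = alpha_i * h + c_i}, where h is the obstacle extension
#' (height or width) plus a security margin and c_i are the nominal
#' early-swing targets.  Only the early-swing goal changes; late swing
#' reverts to balance-law control.
#'
#' @param h_o obstacle extension, m (>= 0, without margin)
#' @param policy "sagittal" (ankle/knee/hip flexion) or "lateral" (hip
#'   abduction)
#' @param nominal nominal early-swing targets (hip pitch, hip roll, knee,
#'   ankle), rad
#' @param alpha per-joint mapping slopes, rad/m, in the same order;
#'   defaults are hand-fitted values
#' @param margin security margin added to h_o, m
#' @param rom_lo,rom_hi joint range-of-motion bounds used for clamping
#' @return adjusted 4-vector of early-swing targets
#' @export
obstacle_targets <- function(h_o, policy = c("sagittal", "lateral"),
                             nominal = c(0.6, 0.05, 1.2, 0.1),
                             alpha = NULL, margin = 0.03,
                             rom_lo = c(-0.35, -0.35, 0, -0.8),
                             rom_hi = c(1.75, 0.35, 2.62, 0.6)) {
  stopifnot(h_o >= 0)
  policy <- match.arg(policy)
  if (is.null(alpha)) {
    alpha <- if (policy == "sagittal") c(2.4, 0, 3.2, 1.2) else c(0, -2.0, 0, 0)
  }
  h <- h_o + if (h_o > 0) margin else 0
  tgt <- alpha * h + nominal
  clamped <- pmin(pmax(tgt, rom_lo), rom_hi)
  if (any(clamped != tgt)) {
    warning("obstacle targets clamped to the joint range of motion")
  }
  clamped
}

#' Walking-speed command
#'
#' Sets the trunk-lean reference of the stance-leg trunk-balance module;
#' larger forward lean produces larger gravitational acceleration and
#' higher walking speed (with lower cadence).
#'
#' @param gait a gait parameter list (see \code{\link{default_gait}})
#' @param lean_deg desired trunk lean reference in degrees (stable band
#'   roughly 6 to 8.5 deg)
#' @return the modified gait parameter list
#' @export
speed_command <- function(gait, lean_deg) {
  gait$th_ref_s <- lean_deg * pi / 180
  gait
}

#' Heading-direction command
#'
#' Constant offset added to the swing-leg hip-roll target while the heading
#' error is outside a tolerance interval; zero inside it.  The offset
#' induces a mild rotational slip of the stance foot that turns the model.
#'
#' @param target_heading,current_heading headings in rad
#' @param offset offset magnitude, rad
#' @param tol tolerance half-width, rad
#' @return signed hip-roll target offset, rad
#' @export
direction_command <- function(target_heading, current_heading,
                              offset = 0.06, tol = 0.04) {
  err <- target_heading - current_heading
  if (abs(err) <= tol) 0 else sign(err) * offset
}
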