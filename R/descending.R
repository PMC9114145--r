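#' Planned accelerations to swing-leg torques
#'
#' Inverse-dynamics step of the internal model: the planned 4-vector of
#' swing-leg joint accelerations is zero-padded to the full 14-DoF
#' coordinate vector (free-body trunk and stance-leg components zero), the
#' equation of motion is evaluated at the delayed state estimates, and the
#' swing-leg block of the resulting torque vector is returned.  Ground
#' contact is deliberately ignored by the internal model.
#'
#' @param body an \code{fg_body}
#' @param acc_swing planned swing-leg accelerations (hip pitch, hip roll,
#'   knee, ankle), rad/s^2
#' @param theta_hat,theta_dot_hat delayed estimates of the full 14-vector
#'   state
#' @param leg "left" or "right"
#' @return 4-vector of desired swing-leg torques, N m
#' @export
accel_to_torques <- function(body, acc_swing, theta_hat, theta_dot_hat,
                             leg = c("left", "right")) {
  leg <- match.arg(leg)
  idx <- if (leg == "left") 7:10 else 11:14
  qdd <- rep(0, 14)
  qdd[idx] <- acc_swing
  tau <- inverse_dynamics(body, theta_hat, theta_dot_hat, qdd)
  tau[idx]
}

#' Non-negative muscle-force distribution
#'
#' Distributes desired joint torques over the muscles by iterating the
#' Moore-Penrose pseudo-inverse of the moment-arm block: the first pass
#' \code{F1 = C+ tau} may contain negative (non-physical) forces; the
#' torque generated by the negative part is re-distributed in the next
#' pass, and the positive parts accumulate.  Seven iterations leave a
#' per-joint torque residual below a few newtons for typical stepping
#' torques, at a fraction of the cost of exact non-negative least squares.
#'
#' @param C moment-arm block (n_dof x n_muscles)
#' @param tau desired torque vector, N m
#' @param iterations number of pseudo-inverse passes
#' @return list with \code{F} (non-negative forces, N), \code{residual}
#'   (torque residual C F - tau), \code{rmse} (per-joint absolute
#'   residual) and \code{iterations}
#' @export
distribute_forces <- function(C, tau, iterations = 7) {
  if (nrow(C) != length(tau)) stop("dimension mismatch between C and tau")
  sv <- svd(C)$d
  if (min(sv) < 1e-10 * max(sv)) {
    warning("moment-arm block is rank-deficient; pseudo-inverse regularized")
  }
  F <- drop(cpp_distribute_forces(C, tau, as.integer(iterations)))
  res <- drop(C %*% F) - tau
  list(F = F, residual = res, rmse = abs(res), iterations = iterations)
}

#' Inverse muscle model: forces to stimulations
#'
#' Inverts the contractile-element force law at the current estimates:
#' \code{S = F / (Fmax f_l(l_ce) f_v(v_ce))}, element-wise, clamped to
#' [0, 1].  Series, parallel and buffer elements and the activation
#' low-pass are neglected (S = A), valid while muscles operate away from
#' their passive engagement lengths.  The denominator is floored so that
#' muscles near their force-generation limits do not request unbounded
#' stimulation.
#'
#' @param muscles an \code{fg_muscles} table (or the 11-row block of one
#'   leg)
#' @param F desired muscle forces, N (>= 0)
#' @param l_ce,v_ce CE length and velocity estimates
#' @param floor lower bound on f_l * f_v
#' @return stimulation vector in [0, 1]
#' @export
forces_to_stimulation <- function(muscles, F, l_ce, v_ce, floor = 0.05) {
  if (any(F < -1e-9)) stop("desired forces must be non-negative")
  cur <- muscle_curves(muscles, l_ce, v_ce)
  den <- pmax(cur[, "f_l"] * cur[, "f_v"], floor) * muscles$Fmax
  unname(pmin(pmax(F / den, 0), 1))
}

#' Reflex inversion: stimulations to descending commands
#'
#' Solves the stretch reflex for the threshold-shift command that will
#' reproduce the desired stimulation: \code{u = (S + h) / K_l - l_ce}.
#' Composing with \code{\link{stretch_reflex}} at zero delay and zero
#' velocity terms returns S exactly.  The command rate u_dot is obtained by
#' filtered differencing across control steps.
#'
#' @param S_des desired stimulations in [0, 1]
#' @param l_ce CE length estimates
#' @param K_l,h reflex length gain and resting level
#' @return descending command vector u (CE-length units)
#' @export
stimulation_to_command <- function(S_des, l_ce, K_l, h) {
  stopifnot(all(K_l > 0))
  (S_des + h) / K_l - l_ce
}
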