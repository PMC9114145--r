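#' Simulate goal-directed swing-leg movements with a fixed trunk
#'
#' The trunk is passively stabilized by fixing its position in space and
#' one leg executes a sequence of goal-directed movements: each goal is a
#' joint configuration (hip pitch, hip roll, knee, ankle) with a movement
#' duration, reached via a continuously replanned minimum-jerk trajectory
#' that is transformed into descending commands and executed through the
#' stretch-reflex / muscle chain.
#'
#' @param model an \code{fg_model}
#' @param goals matrix with columns (hip, roll, knee, ankle, duration); one
#'   row per movement segment, executed back to back
#' @param leg "left" or "right"
#' @param q0_leg initial leg configuration, rad
#' @param settle hold time at the initial configuration before the first
#'   movement, s (lets the initially slack muscles engage)
#' @return object of class \code{fg_swing}: control-rate logs of realized
#'   and planned joint trajectories, ankle paths, desired torques, torque
#'   residuals of the force distribution, muscle forces, stimulations and
#'   descending commands
#' @export
simulate_swing <- function(model, goals, leg = c("left", "right"),
                           q0_leg = c(0.3, 0, 0.3, 0), settle = 0.5) {
  leg <- match.arg(leg)
  goals <- as.matrix(goals)
  stopifnot(ncol(goals) == 5, all(goals[, 5] > 0))
  out <- cpp_simulate_swing(unclass(model$body), mtbl_list(model$muscles),
                            model$ctrl, if (leg == "left") 1L else 2L,
                            as.numeric(q0_leg), goals, settle)
  out$leg <- leg
  out$goals <- goals
  out$settle <- settle
  colnames(out$theta) <- colnames(out$theta_plan) <-
    c("hip", "roll", "knee", "ankle")
  class(out) <- "fg_swing"
  out
}

#' Simulate walking
#'
#' Full neuromuscular walking simulation: the finite state machine switches
#' each leg between stance (five spinal reflex modules) and swing
#' (planned, goal-directed movement to balance-law targets).  Optional
#' protocol elements: a force pulse at the trunk, an obstacle that
#' retargets one early-swing phase, and heading-direction control.
#'
#' @param model an \code{fg_model}
#' @param duration simulated time, s
#' @param lean0 initial trunk pitch, rad
#' @param v0 initial forward velocity, m/s
#' @param swing_first which leg starts in early swing
#' @param perturb \code{list(hs_index=, force=c(fx,fy,fz), dur=)}: force
#'   pulse at the trunk center starting at the k-th heel-strike
#' @param obstacle \code{list(swing_index=, targets=)}: early-swing target
#'   override for the k-th swing phase (see
#'   \code{\link{obstacle_targets}})
#' @param direction \code{list(target=, offset=, tol=)}: heading control
#' @param log_stims record muscle stimulations
#' @param log_every decimation of the control-rate logs
#' @param state0 optional explicit initial \code{fg_state}
#' @param act0 initial muscle activation (launching from quiet stance needs
#'   pre-activated anti-gravity muscles; the tone decays within ~50 ms)
#' @return object of class \code{fg_walk} with trajectory logs, ground
#'   reaction forces, phase sequence, heel-strike table, fall flag and the
#'   gait steadiness measure
#' @export
simulate_walk <- function(model, duration = 30, lean0 = 0.06, v0 = 0.35,
                          swing_first = c("right", "left"), perturb = NULL,
                          obstacle = NULL, direction = NULL,
                          log_stims = FALSE, log_every = 10L,
                          state0 = NULL, act0 = 0.3) {
  swing_first <- match.arg(swing_first)
  model$ctrl$act0 <- act0
  if (is.null(state0)) {
    state0 <- standing_state(model$body, lean = lean0)
    state0$theta_dot[1] <- v0
  }
  opts <- list(log_stims = log_stims, log_every = as.integer(log_every))
  if (!is.null(perturb)) opts$perturb <- perturb
  if (!is.null(obstacle)) opts$obstacle <- obstacle
  if (!is.null(direction)) opts$direction <- direction
  out <- cpp_simulate_walk(unclass(model$body), mtbl_list(model$muscles),
                           model$ctrl, model$gait, duration, state0$theta,
                           state0$theta_dot,
                           if (swing_first == "left") 1L else 2L, opts)
  colnames(out$q) <- colnames(out$qd) <-
    c("x", "y", "z", "yaw", "pitch", "roll",
      paste0("L_", c("hip", "roll", "knee", "ankle")),
      paste0("R_", c("hip", "roll", "knee", "ankle")))
  colnames(out$grf) <- c("L_fx", "L_fy", "L_fz", "R_fx", "R_fy", "R_fz")
  colnames(out$misc) <- c("cop_x", "cop_y", "d_sag", "d_frontal",
                          "com_x", "com_y", "com_z", "fz_total")
  if (nrow(out$heel_strikes) > 0) {
    colnames(out$heel_strikes) <- c("t", "leg", "x", "y")
  }
  out$duration <- duration
  class(out) <- "fg_walk"
  out
}

#' @export
print.fg_walk <- function(x, ...) {
  cat("flexgait walking simulation\n")
  cat(sprintf("  duration: %.1f s%s\n", x$duration,
              if (x$fell) sprintf(" (fell at t = %.2f s, x = %.2f m)",
                                  x$t_fall, x$x_fall) else ""))
  n <- nrow(x$q)
  if (n > 1 && !x$fell) {
    cat(sprintf("  forward displacement: %.2f m\n", x$q[n, "x"] - x$q[1, "x"]))
    cat(sprintf("  heel strikes: %d\n", nrow(x$heel_strikes)))
    if (is.finite(x$d_steady)) {
      cat(sprintf("  steadiness d: %.3f\n", x$d_steady))
    }
  }
  invisible(x)
}

#' @export
print.fg_swing <- function(x, ...) {
  cat("flexgait swing-leg simulation\n")
  cat(sprintf("  leg: %s, %d movement segment(s), %.2f s simulated\n",
              x$leg, nrow(x$goals), max(x$t) + diff(x$t[1:2])))
  err <- sqrt(colMeans((x$theta - x$theta_plan)^2))
  cat("  joint RMSE vs plan (rad):",
      paste(sprintf("%s %.4f", colnames(x$theta), err), collapse = ", "),
      "\n")
  invisible(x)
}
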