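#' Normalized root-mean-squared error
#'
#' RMSE between a realized and a planned series, divided by a
#' normalization range (a joint's range of motion for joint-space series).
#'
#' @param realized,planned equal-length numeric series (or matrices with
#'   matching dimensions, pooled over all entries)
#' @param range normalization constant (> 0)
#' @export
compute_nrmse <- function(realized, planned, range) {
  if (length(realized) != length(planned)) {
    stop("series lengths differ")
  }
  if (!is.finite(range) || range <= 0) {
    stop("invalid normalization range")
  }
  sqrt(mean((as.numeric(realized) - as.numeric(planned))^2)) / range
}

# world ankle position for a leg configuration with the trunk frame at a
# fixed reference pose
ankle_position <- function(body, q_leg, leg = "left") {
  q <- rep(0, 14)
  q[3] <- body$trunk_h0 + 1
  idx <- if (leg == "left") 7:10 else 11:14
  q[idx] <- q_leg
  org <- joint_centers(body, q)
  org[if (leg == "left") 10 else 14, ]
}

#' Inverse kinematics for the leg
#'
#' Damped least-squares iteration mapping a workspace ankle position to a
#' joint configuration (the 4-DoF leg is redundant for a 3-D point; the
#' solution closest to the start configuration is returned).
#'
#' @param body an \code{fg_body}
#' @param target ankle position in the trunk-fixed reference frame used by
#'   \code{\link{simulate_swing}} (trunk at x = y = 0, pelvis at
#'   trunk_h0 + 1)
#' @param q0_leg starting configuration
#' @param leg "left" or "right"
#' @param tol convergence tolerance on the position error, m
#' @param max_iter iteration budget
#' @return list with \code{q_leg}, \code{err} (final position error) and
#'   \code{converged}
#' @export
leg_ik <- function(body, target, q0_leg = c(0.3, 0, 0.6, 0),
                   leg = c("left", "right"), tol = 1e-5, max_iter = 200) {
  leg <- match.arg(leg)
  q <- q0_leg
  lo <- body$limits$lo
  hi <- body$limits$hi
  lambda <- 0.05
  for (it in seq_len(max_iter)) {
    p <- ankle_position(body, q, leg)
    e <- target - p
    if (sqrt(sum(e^2)) < tol) {
      return(list(q_leg = q, err = sqrt(sum(e^2)), converged = TRUE))
    }
    J <- matrix(0, 3, 4)
    h <- 1e-6
    for (j in 1:4) {
      qp <- q
      qp[j] <- qp[j] + h
      J[, j] <- (ankle_position(body, qp, leg) - p) / h
    }
    A <- J %*% t(J) + lambda^2 * diag(3)
    dq <- drop(t(J) %*% solve(A, e))
    q <- pmin(pmax(q + dq, lo), hi)
  }
  p <- ankle_position(body, q, leg)
  list(q_leg = q, err = sqrt(sum((target - p)^2)), converged = FALSE)
}

#' Default center-out reaching targets
#'
#' Twelve workspace target positions for the ankle around a central leg
#' configuration, chosen to cover a large portion of the workspace with
#' straight-line path lengths between roughly 0.20 and 0.55 m.
#'
#' @param body an \code{fg_body}
#' @param center_leg central leg configuration
#' @param leg which leg
#' @return list with the \code{center} ankle position and a 12 x 3 matrix
#'   of \code{targets}
#' @export
center_out_targets <- function(body, center_leg = c(0.45, 0, 0.7, 0),
                               leg = "left") {
  p0 <- ankle_position(body, center_leg, leg)
  # reachable by construction: targets are the ankle positions of fixed
  # joint-space configurations spread over the leg's workspace
  cfg <- rbind(c(0.90, 0.00, 0.70, 0.00),   # hip swing forward
               c(0.08, 0.00, 0.70, 0.00),   # hip swing backward
               c(0.45, 0.00, 1.40, 0.20),   # deep knee flexion
               c(0.45, 0.00, 0.32, -0.08),  # knee extension
               c(1.00, 0.00, 1.32, 0.10),   # flexed forward lift
               c(-0.18, 0.00, 0.38, -0.15), # extended backward
               c(0.80, 0.12, 0.95, 0.00),   # forward + adduction
               c(0.65, -0.20, 0.45, 0.00),  # abducted
               c(1.28, 0.00, 1.05, 0.12),   # far forward lift
               c(0.02, 0.00, 0.45, -0.20),  # far backward-down
               c(0.60, 0.24, 0.85, 0.00),   # adducted lift
               c(0.28, -0.24, 1.05, 0.10))  # abducted flexion
  targets <- t(apply(cfg, 1, function(q) ankle_position(body, q, leg)))
  list(center = p0, targets = targets, configs = cfg)
}

#' Center-out reaching experiment
#'
#' With the trunk fixed in space, the foot performs a sequence of
#' center-out reaching movements to twelve target locations, each followed
#' by a return to the center, at 0.5 s per movement segment.  Targets are
#' workspace ankle positions converted to joint space by
#' \code{\link{leg_ik}}.
#'
#' @param model an \code{fg_model}
#' @param targets 12 x 3 matrix of ankle targets (default fixture from
#'   \code{\link{center_out_targets}})
#' @param T_seg movement segment duration, s
#' @param leg which leg
#' @return list with the swing-simulation object, realized and planned
#'   ankle paths, the ankle-path NRMSE, per-segment endpoint errors and
#'   path lengths
#' @export
run_center_out <- function(model, targets = NULL, T_seg = 0.5,
                           leg = "left") {
  body <- model$body
  center_leg <- c(0.45, 0, 0.7, 0)
  if (is.null(targets)) {
    targets <- center_out_targets(body, center_leg, leg)$targets
  }
  qc <- center_leg
  goal_rows <- list()
  qprev <- qc
  skipped <- integer(0)
  for (i in seq_len(nrow(targets))) {
    ik <- leg_ik(body, targets[i, ], q0_leg = qc, leg = leg)
    if (!ik$converged && ik$err > 5e-3) {
      warning(sprintf("target %d unreachable (err %.1f mm); skipped", i,
                      1000 * ik$err))
      skipped <- c(skipped, i)
      next
    }
    goal_rows[[length(goal_rows) + 1]] <- c(ik$q_leg, T_seg)
    goal_rows[[length(goal_rows) + 1]] <- c(qc, T_seg)
    qprev <- qc
  }
  goals <- do.call(rbind, goal_rows)
  sw <- simulate_swing(model, goals, leg = leg, q0_leg = qc, settle = 0.5)
  sel <- sw$t >= sw$settle
  err3 <- sw$ankle[sel, ] - sw$ankle_plan[sel, ]
  rng <- apply(sw$ankle_plan[sel, ], 2, function(x) diff(range(x)))
  L <- sqrt(sum(rng^2))
  nrmse <- sqrt(mean(rowSums(err3^2))) / L
  # endpoint error at the end of each segment
  seg <- sw$segment
  ends <- which(diff(seg) > 0)
  ep <- sqrt(rowSums((sw$ankle[ends, , drop = FALSE] -
                        sw$ankle_plan[ends, , drop = FALSE])^2))
  # planned path length per segment
  pl <- tapply(seq_along(seg)[sel], seg[sel], function(ix) {
    sum(sqrt(rowSums(diff(sw$ankle_plan[ix, , drop = FALSE])^2)))
  })
  list(swing = sw, nrmse_ankle_path = nrmse, endpoint_err = ep,
       path_lengths = as.numeric(pl), skipped = skipped,
       norm_range = L)
}

#' Sinusoid-tracking experiment
#'
#' The four swing-leg joints simultaneously follow 1 Hz oscillations for
#' 10 s, implemented as repeated goal-directed movements between two
#' joint-space configurations (0.5 s per half-cycle) with amplitudes that
#' roughly capture a stepping movement.
#'
#' @param model an \code{fg_model}
#' @param qa,qb the two joint configurations
#' @param duration total time, s
#' @param leg which leg
#' @return list with the swing object and per-joint NRMSE (normalized to
#'   the range of motion)
#' @export
run_sinusoid <- function(model, qa = c(0.1, -0.05, 0.1, -0.2),
                         qb = c(0.7, 0.10, 1.1, 0.2), duration = 10,
                         leg = "left") {
  ncyc <- round(duration / 1.0)
  goals <- do.call(rbind, rep(list(rbind(c(qb, 0.5), c(qa, 0.5))), ncyc))
  sw <- simulate_swing(model, goals, leg = leg, q0_leg = qa, settle = 0.5)
  sel <- sw$t >= sw$settle
  rom <- model$body$limits$hi - model$body$limits$lo
  nrmse <- vapply(1:4, function(j) {
    compute_nrmse(sw$theta[sel, j], sw$theta_plan[sel, j], rom[j])
  }, numeric(1))
  names(nrmse) <- c("hip", "roll", "knee", "ankle")
  list(swing = sw, nrmse = nrmse)
}

# draw a random target over 15-85% of each joint's range of motion,
# excluding configurations that would drive a CE below its slack-adjusted
# minimum length
draw_target <- function(model, leg = "left") {
  lo <- model$body$limits$lo
  hi <- model$body$limits$hi
  mus <- model$muscles[model$muscles$leg == (if (leg == "left") 0 else 1), ]
  repeat {
    q <- lo + runif(4, 0.15, 0.85) * (hi - lo)
    qf <- rep(0, 14)
    qf[if (leg == "left") 7:10 else 11:14] <- q
    g <- muscle_geometry(model$muscles, qf)
    lm <- g$l_mtu[rownames(mus)]
    if (all(lm - mus$lslack > 0.4 * mus$lopt)) return(q)
  }
}

#' Randomized reaching experiment
#'
#' Goal-directed movements between random joint-space configurations drawn
#' uniformly over 15-85% of each joint's range of motion (excluding
#' configurations that slacken a muscle below its operating range), for a
#' set of movement times, with the trunk fixed.  Performance is the
#' per-joint NRMSE between realized and planned trajectories.
#'
#' @param model an \code{fg_model}
#' @param times movement times, s
#' @param n_per_time movements per movement time
#' @param seed RNG seed
#' @param leg which leg
#' @return list with a per-time matrix of mean per-joint NRMSE and the raw
#'   per-movement values
#' @export
run_random_reaches <- function(model, times = seq(0.1, 1.0, length.out = 10),
                               n_per_time = 10, seed = 1, leg = "left") {
  set.seed(seed)
  rom <- model$body$limits$hi - model$body$limits$lo
  res <- array(NA_real_, c(length(times), n_per_time, 4))
  for (ti in seq_along(times)) {
    q0 <- draw_target(model, leg)
    goals <- cbind(t(replicate(n_per_time, draw_target(model, leg))),
                   times[ti])
    sw <- simulate_swing(model, goals, leg = leg, q0_leg = q0, settle = 0.5)
    for (mi in seq_len(n_per_time)) {
      ix <- which(sw$segment == mi - 1 & sw$t >= sw$settle)
      for (j in 1:4) {
        res[ti, mi, j] <- compute_nrmse(sw$theta[ix, j],
                                        sw$theta_plan[ix, j], rom[j])
      }
    }
  }
  mean_nrmse <- apply(res, c(1, 3), mean)
  dimnames(mean_nrmse) <- list(sprintf("%.2f", times),
                               c("hip", "roll", "knee", "ankle"))
  list(times = times, mean_nrmse = mean_nrmse, raw = res)
}

#' Walking experiment with gait summary
#'
#' @param model an \code{fg_model}
#' @param duration simulated time, s
#' @param discard_steps heel strikes discarded as transient before
#'   computing speed and cadence
#' @param ... passed to \code{\link{simulate_walk}}
#' @return list with the walk object, mean forward speed (m/s), cadence
#'   (steps/min), step lengths/widths/durations, left/right means, and
#'   gait-cycle-averaged joint trajectories (100 points per cycle, keyed
#'   on left heel-strike)
#' @export
run_walk <- function(model, duration = 30, discard_steps = 2, ...) {
  w <- simulate_walk(model, duration = duration, ...)
  hs <- w$heel_strikes
  out <- list(walk = w, fell = w$fell, t_fall = w$t_fall)
  if (nrow(hs) <= discard_steps + 2) {
    out$speed <- NA_real_
    return(out)
  }
  t0 <- hs[discard_steps + 1, "t"]
  n <- nrow(w$q)
  tend <- w$t[n]
  i0 <- which.min(abs(w$t - t0))
  out$speed <- (w$q[n, "x"] - w$q[i0, "x"]) / (tend - t0)
  steps <- hs[-seq_len(discard_steps), , drop = FALSE]
  out$cadence <- 60 * (nrow(steps) - 1) / (steps[nrow(steps), "t"] -
                                             steps[1, "t"])
  ds <- diff(steps[, "x"])
  out$step_length <- ds
  out$step_width <- abs(diff(steps[, "y"]))
  out$step_duration <- diff(steps[, "t"])
  out$step_leg <- steps[-1, "leg"]
  # gait-cycle averages keyed on left heel-strikes
  lhs <- steps[steps[, "leg"] == 0, "t"]
  if (length(lhs) >= 3) {
    cols <- c("L_hip", "L_roll", "L_knee", "L_ankle")
    cyc <- array(NA_real_, c(length(lhs) - 1, 100, length(cols)))
    for (ci in seq_len(length(lhs) - 1)) {
      tt <- seq(lhs[ci], lhs[ci + 1], length.out = 100)
      for (j in seq_along(cols)) {
        cyc[ci, , j] <- approx(w$t, w$q[, cols[j]], tt)$y
      }
    }
    mcyc <- apply(cyc, c(2, 3), mean)
    scyc <- apply(cyc, c(2, 3), sd)
    colnames(mcyc) <- colnames(scyc) <- cols
    out$cycle_mean <- mcyc
    out$cycle_sd <- scyc
  }
  out
}

#' Push-recovery perturbation experiment
#'
#' Force pulses of increasing strength applied at the trunk center,
#' starting at foot contact and lasting 0.2 s, in a given direction.
#' The staircase increases the amplitude in coarse steps until the model
#' falls, then refines from the largest tolerated amplitude in fine steps.
#'
#' @param model an \code{fg_model}
#' @param direction one of "forward", "backward", "medial", "lateral"
#'   (medial/lateral defined for a pulse during right-leg stance)
#' @param start,step,refine staircase amplitudes, N
#' @param dur pulse duration, s
#' @param hs_index heel strike at which the pulse starts
#' @param duration total simulated time per trial, s
#' @param max_force safety bound on the search, N
#' @return list with the tolerated amplitude and the trial table
#' @export
run_perturbations <- function(model, direction = c("forward", "backward",
                                                   "medial", "lateral"),
                              start = 50, step = 50, refine = 5, dur = 0.2,
                              hs_index = 6, duration = 14, max_force = 600) {
  direction <- match.arg(direction)
  dirv <- switch(direction,
                 forward = c(1, 0, 0), backward = c(-1, 0, 0),
                 medial = c(0, 1, 0), lateral = c(0, -1, 0))
  trial <- function(amp) {
    w <- simulate_walk(model, duration = duration, log_every = 100L,
                       perturb = list(hs_index = as.integer(hs_index),
                                      force = amp * dirv, dur = dur))
    !w$fell
  }
  trials <- data.frame(amp = numeric(0), survived = logical(0))
  amp <- start
  last_ok <- 0
  while (amp <= max_force) {
    ok <- trial(amp)
    trials <- rbind(trials, data.frame(amp = amp, survived = ok))
    if (!ok) break
    last_ok <- amp
    amp <- amp + step
  }
  if (amp > max_force) {
    return(list(tolerated = last_ok, trials = trials, censored = TRUE))
  }
  amp <- last_ok + refine
  while (amp < last_ok + step) {
    ok <- trial(amp)
    trials <- rbind(trials, data.frame(amp = amp, survived = ok))
    if (!ok) break
    last_ok <- amp
    amp <- amp + refine
  }
  list(tolerated = last_ok, trials = trials, censored = FALSE)
}

# world position of the balls of the foot (mean of the two forefoot
# contact points) for every logged sample
forefoot_path <- function(model, w, leg = "left") {
  pts <- model$body$contact$points[3:4, ]
  pl <- colMeans(pts)
  n <- nrow(w$q)
  out <- matrix(NA_real_, n, 3)
  body <- unclass(model$body)
  row <- if (leg == "left") 10 else 14
  for (i in seq_len(n)) {
    org <- cpp_fk_points(body, w$q[i, ])$origins
    # foot frame orientation is ignored for the offset (small-angle foot)
    out[i, ] <- org[row, ] + pl
  }
  out
}

#' Obstacle-avoidance experiment
#'
#' During steady walking, the early-swing goal configuration of one step
#' is retargeted by the linear obstacle mapping
#' (\code{\link{obstacle_targets}}) to lift the swing leg over (sagittal)
#' or shift it around (medial-lateral) an obstacle.  The outcome is the
#' deviation of the forefoot trajectory from an unobstructed baseline walk.
#'
#' @param model an \code{fg_model}
#' @param h_o obstacle extension (height or width), m
#' @param policy "sagittal" or "lateral"
#' @param swing_index which swing phase of the affected leg is retargeted
#' @param duration simulated time, s
#' @param margin security margin, m
#' @return list with success flag, peak deviation (m), deviation profile,
#'   fall flag and the two walk objects
#' @export
run_obstacle <- function(model, h_o = 0.15,
                         policy = c("sagittal", "lateral"),
                         swing_index = 5, duration = 12, margin = 0.03) {
  policy <- match.arg(policy)
  base <- simulate_walk(model, duration = duration, log_every = 20L)
  tgt <- obstacle_targets(h_o, policy, nominal = model$gait$early_tgt,
                          margin = margin,
                          rom_lo = model$body$limits$lo,
                          rom_hi = model$body$limits$hi)
  obs <- simulate_walk(model, duration = duration, log_every = 20L,
                       obstacle = list(swing_index = as.integer(swing_index),
                                       targets = tgt))
  # the retargeted swing phase belongs to the leg that enters its
  # swing_index-th swing; with right leg swinging first, odd counts are
  # right-leg swings for both legs' counters -- compare forefoot paths of
  # both legs and take the larger deviation
  axis <- if (policy == "sagittal") 3 else 2
  nmin <- min(nrow(base$q), nrow(obs$q))
  dev_best <- NULL
  for (leg in c("left", "right")) {
    pb <- forefoot_path(model, base, leg)[seq_len(nmin), axis]
    po <- forefoot_path(model, obs, leg)[seq_len(nmin), axis]
    d <- po - pb
    if (is.null(dev_best) || max(abs(d), na.rm = TRUE) >
        max(abs(dev_best), na.rm = TRUE)) {
      dev_best <- d
    }
  }
  peak <- max(abs(dev_best), na.rm = TRUE)
  list(success = !obs$fell && peak >= h_o, peak_deviation = peak,
       deviation = dev_best, t = base$t[seq_len(nmin)],
       fell = obs$fell, baseline = base, obstructed = obs)
}

#' Walking-speed sweep over trunk-lean references
#'
#' Simulates walking for a set of trunk-lean reference values of the
#' stance-leg trunk-balance module and reports the resulting mean forward
#' speed and cadence (speed increases and cadence decreases with lean).
#'
#' @param model an \code{fg_model}
#' @param leans_deg trunk-lean references, degrees
#' @param duration simulated time per lean, s
#' @return data.frame with lean, speed, cadence, fell
#' @export
run_speed_sweep <- function(model, leans_deg = seq(6, 8.5, length.out = 6),
                            duration = 40) {
  rows <- lapply(leans_deg, function(ld) {
    mi <- model
    mi$gait <- speed_command(mi$gait, ld)
    rw <- run_walk(mi, duration = duration, log_every = 100L)
    data.frame(lean_deg = ld, speed = rw$speed,
               cadence = if (is.null(rw$cadence)) NA else rw$cadence,
               fell = rw$fell)
  })
  do.call(rbind, rows)
}

#' Heading-direction experiment
#'
#' Walks with a constant hip-roll target offset applied while the heading
#' error exceeds a tolerance, turning the model toward a target heading.
#'
#' @param model an \code{fg_model}
#' @param target_deg target heading, degrees
#' @param duration simulated time, s
#' @param offset,tol hip-roll offset and heading tolerance, rad
#' @return list with the walk object, the heading trajectory and the final
#'   heading error (rad)
#' @export
run_direction <- function(model, target_deg = 20, duration = 40,
                          offset = 0.06, tol = 0.05) {
  w <- simulate_walk(model, duration = duration, log_every = 50L,
                     direction = list(target = target_deg * pi / 180,
                                      offset = offset, tol = tol))
  err <- target_deg * pi / 180 - w$q[nrow(w$q), "yaw"]
  list(walk = w, t = w$t, heading = w$q[, "yaw"], final_error = err)
}
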