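#' Generic stretch reflex
#'
#' Alpha-motorneuron stimulation from muscle-spindle signals, modulated by
#' the descending command: \code{S = [K_l (l_ce + u) + K_v (v_ce + u_dot)
#' - h]+}, rectified and clamped to \code{[S_min, 1]}.  The command u acts
#' as a threshold shift of the length feedback; its rate u_dot provides
#' relative damping and the initial stimulation burst of a commanded
#' contraction.
#'
#' @param l_ce,v_ce delayed spindle estimates of CE stretch and stretch rate
#' @param u,u_dot descending command (CE-length units) and its rate
#' @param K_l,K_v length and velocity gains (K_l > 0, K_v >= 0)
#' @param h motorneuron resting level
#' @param S_min baseline stimulation tone (default 0.01)
#' @return stimulation in [S_min, 1]; vectorized over its inputs
#' @export
stretch_reflex <- function(l_ce, v_ce, u, u_dot, K_l, K_v, h, S_min = 0.01) {
  stopifnot(all(K_l > 0), all(K_v >= 0), all(h >= 0))
  n <- max(length(l_ce), length(u))
  args <- data.frame(l_ce = rep_len(l_ce, n), v_ce = rep_len(v_ce, n),
                     u = rep_len(u, n), u_dot = rep_len(u_dot, n),
                     K_l = rep_len(K_l, n), K_v = rep_len(K_v, n),
                     h = rep_len(h, n))
  vapply(seq_len(n), function(i) {
    cpp_stretch_reflex(args$l_ce[i], args$v_ce[i], args$u[i], args$u_dot[i],
                       args$K_l[i], args$K_v[i], args$h[i], S_min)
  }, numeric(1))
}

#' Transport delay line
#'
#' Exact fixed transport delay of a sampled signal: \code{y[k] = x[k - d]}
#' with the buffer initialized to the first sample.  The delay must be an
#' integer multiple of the sampling step.
#'
#' @param x sampled signal
#' @param delay delay in seconds
#' @param dt sampling step in seconds
#' @export
delay_signal <- function(x, delay, dt) {
  stopifnot(delay >= 0, dt > 0)
  steps <- delay / dt
  if (abs(steps - round(steps)) > 1e-9) {
    stop("delay must be an integer multiple of dt")
  }
  drop(cpp_delay_signal(as.numeric(x), as.integer(round(steps))))
}

#' Stance-leg reflex module stimulations
#'
#' Stimulations for the 11 muscles of a stance leg from the five functional
#' spinal modules: (1) positive force feedback on the anti-gravity
#' extensors (VAS, SOL, GAS) producing compliant leg behavior, (2) knee
#' overextension prevention (VAS suppression, BFSH recruitment), (3)
#' trunk-upright PD feedback distributed to the hip muscles and weighted by
#' the leg's load share, (4) compensation of interaction torques from the
#' contralateral swing leg at the hip, and (5) ankle dorsiflexion through
#' TA length feedback suppressed by SOL force.  The generic stretch reflex
#' is not active during stance.
#'
#' @param gains named list of module gains (see \code{\link{default_gait}};
#'   must include \code{Smin})
#' @param signals named list of delayed sensor values: normalized muscle
#'   forces \code{Fn_vas}, \code{Fn_sol}, \code{Fn_gas}; \code{knee},
#'   \code{dknee}; trunk \code{pitch}, \code{dpitch} and side-adjusted
#'   \code{roll_rel}, \code{droll_rel}; leg \code{load} share;
#'   contralateral swing hip torque \code{tau_sw_hip}; normalized TA CE
#'   length \code{lce_ta_norm}
#' @return stimulation vector of length 11 in [Smin, 1], muscle order
#'   HFL GLU HAM RF VAS BFSH GAS SOL TA HAB HAD
#' @export
stance_stimulations <- function(gains, signals) {
  S <- drop(cpp_stance_stims(gains, signals))
  names(S) <- c("HFL", "GLU", "HAM", "RF", "VAS", "BFSH", "GAS", "SOL",
                "TA", "HAB", "HAD")
  S
}
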