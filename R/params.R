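#' Default reflex parameterization
#'
#' Reflex gains are tuned per muscle group: K_l is expressed as a
#' dimensionless scale over the inverse of the muscle's operating length
#' range (\code{K_l = kl / (w * lopt)}), K_v as a damping time scale
#' relative to K_l (\code{K_v = kv * K_l}), and h is the motorneuron
#' resting level.  Groups: HFL, GLU, HAM, RF, VAS, BFSH, plantarflexors
#' (GAS + SOL), TA, and the roll muscles (HAB + HAD); both legs share the
#' same gains.
#'
#' @return named list with kl, kv, h vectors of length 9
#' @export
default_reflex <- function() {
  groups <- c("HFL", "GLU", "HAM", "RF", "VAS", "BFSH", "PF", "TA", "ROLL")
  kl <- stats::setNames(rep(0.8, 9), groups)
  kl["TA"] <- 1.6  # the light foot needs a stiffer dorsiflexor servo
  kv <- stats::setNames(rep(0.02, 9), groups)
  kv["ROLL"] <- 0.05  # extra damping for the short, stiff roll muscles
  kv[c("VAS", "BFSH")] <- 0.05
  kv["HAM"] <- 0.04   # knee-spanning muscles damp the fast shank
  list(groups = groups,
       kl = kl,
       kv = kv,
       h = stats::setNames(rep(0.5, 9), groups))
}

# muscle name (without side suffix) -> reflex group
reflex_group_of <- function(name) {
  base <- sub("_[LR]$", "", name)
  map <- c(HFL = "HFL", GLU = "GLU", HAM = "HAM", RF = "RF", VAS = "VAS",
           BFSH = "BFSH", GAS = "PF", SOL = "PF", TA = "TA",
           HAB = "ROLL", HAD = "ROLL")
  unname(map[base])
}

#' Low-level controller settings
#'
#' Sampling rates, sensor transport delays and the fixed internal-model
#' constants of the descending pathway.  The plant integrates at
#' \code{dt} = 0.1 ms and the control chain runs every \code{nsub} plant
#' steps (1 kHz).  Spindle/Golgi delays are 10 ms for hip, 15 ms for knee
#' and 25 ms for ankle pathways; joint-state estimates use the same
#' segment-wise delays.
#'
#' @param muscles an \code{fg_muscles} table
#' @param reflex reflex parameterization from \code{\link{default_reflex}}
#' @return list consumed by the simulation core
#' @export
default_ctrl <- function(muscles = default_muscles(),
                         reflex = default_reflex()) {
  grp <- reflex_group_of(muscles$name)
  Kl <- reflex$kl[grp] / (muscles$w * muscles$lopt)
  Kv <- reflex$kv[grp] * Kl
  h <- reflex$h[grp]
  base <- sub("_[LR]$", "", muscles$name)
  dly_ms <- c(HFL = 10, GLU = 10, HAM = 10, RF = 10, VAS = 15, BFSH = 15,
              GAS = 25, SOL = 25, TA = 25, HAB = 10, HAD = 10)[base]
  list(
    dt = 1e-4, nsub = 10L,
    Kl = unname(Kl), Kv = unname(Kv), h = unname(h),
    Smin = 0.01,
    delay_mus = as.integer(unname(dly_ms)),
    delay_q = as.integer(c(rep(10, 6), rep(c(10, 10, 15, 25), 2))),
    flfv_floor = 0.05, npinv = 7L, udot_tau = 0.005,
    freeze = 0.03, act0 = 0.01, acc_max = 400, acc_tau = 0.02,
    u_preview = 0.04
  )
}

#' Default gait-level controller parameters
#'
#' Balance-law gains, swing-phase goal configurations and target times, and
#' the five stance reflex module gains.  These are the free parameters of
#' the walking controller (together with the reflex gains of
#' \code{\link{default_reflex}}); the shipped values are the result of the
#' package's own tuning run and produce steady walking at about 1.3 m/s.
#'
#' @return named list of gait parameters
#' @export
default_gait <- function() {
  list(
    # balance law (sagittal / frontal)
    phi0_s = 0.3, cd_s = 0.4, cv_s = 0.25,
    phi0_f = 0.08, cd_f = 1.5, cv_f = 0.4,
    delay_bal = 100L, vfilt_tau = 0.02,
    # swing goals: early-swing (mid-swing) configuration and late-swing
    # knee/ankle targets; hip targets in late swing come from the balance law
    early_tgt = c(0.6, 0.0, 1.2, 0.1),
    T_early = 0.3, T_early_p = 0.3, T_late = 0.35,
    late_knee = 0.15, late_ankle = 0.05,
    bal_early = 0L,
    # stance modules
    g1_vas = 2.5, g1_sol = 1.5, g1_gas = 0.6,
    ko_phi = 0.3, ko_vas = 2.0, ko_bfsh = 1.0,
    gp_s = 5.0, gd_s = 1.0, th_ref_s = 7 * pi / 180,
    gp_f = 4.0, gd_f = 0.6,
    g4 = 0.5,
    g_ta = 1.5, loff_ta = 0.95, gsup_ta = 1.2,
    delay_stance = 20L, delay_trunk = 40L,
    contact_thresh = 50, load_thresh = 250, fall_frac = 0.6
  )
}

#' Assemble a complete model
#'
#' Bundles body, muscle table, reflex parameterization, low-level control
#' settings and gait parameters into one object used by all simulation
#' entry points.
#'
#' @param body an \code{fg_body}
#' @param muscles an \code{fg_muscles} table
#' @param reflex reflex gains (see \code{\link{default_reflex}})
#' @param gait gait parameters (see \code{\link{default_gait}})
#' @param ctrl low-level control settings; rebuilt from \code{reflex} if
#'   missing
#' @param params optional 55-parameter vector applied on top of the
#'   structural defaults; the shipped tuned set
#'   (\code{\link{shipped_params}}) by default, NULL for untuned defaults
#' @export
fg_model <- function(body = default_body(), muscles = default_muscles(),
                     reflex = default_reflex(), gait = default_gait(),
                     ctrl = NULL, params = shipped_params()) {
  if (is.null(ctrl)) ctrl <- default_ctrl(muscles, reflex)
  m <- structure(list(body = body, muscles = muscles, reflex = reflex,
                      gait = gait, ctrl = ctrl),
                 class = "fg_model")
  if (!is.null(params)) m <- vector_to_params(m, params)
  m
}

# ---------------------------------------------------------------------------
# the 55 free parameters
# ---------------------------------------------------------------------------

param_names <- function() {
  c("phi0_s", "cd_s", "cv_s", "phi0_f", "cd_f", "cv_f",
    "early_hip", "early_roll", "early_knee", "early_ankle",
    "late_knee", "late_ankle", "T_late", "T_early_p",
    "g1_vas", "g1_sol", "g1_gas", "ko_phi", "ko_vas", "ko_bfsh",
    "gp_s", "gd_s", "th_ref_s", "gp_f", "gd_f", "g4",
    "g_ta", "gsup_ta",
    paste0("kl_", default_reflex()$groups),
    paste0("kv_", default_reflex()$groups),
    paste0("h_", default_reflex()$groups))
}

#' The free controller parameters as a named vector
#'
#' The 55 parameters tuned by evolutionary optimization: 6 balance gains,
#' 7 swing-goal values and times, 15 stance-module gains, and 27 reflex
#' gains (K_l, K_v, h for 9 muscle groups).  The mapping between this
#' vector and the model's parameter lists is bijective.
#'
#' @param model an \code{fg_model}
#' @return named numeric vector of length 55
#' @export
params_to_vector <- function(model) {
  g <- model$gait
  r <- model$reflex
  v <- c(g$phi0_s, g$cd_s, g$cv_s, g$phi0_f, g$cd_f, g$cv_f,
         g$early_tgt, g$late_knee, g$late_ankle, g$T_late, g$T_early_p,
         g$g1_vas, g$g1_sol, g$g1_gas, g$ko_phi, g$ko_vas, g$ko_bfsh,
         g$gp_s, g$gd_s, g$th_ref_s, g$gp_f, g$gd_f, g$g4,
         g$g_ta, g$gsup_ta,
         unname(r$kl), unname(r$kv), unname(r$h))
  stats::setNames(v, param_names())
}

#' Rebuild a model from a parameter vector
#'
#' @param model an \code{fg_model} providing the fixed structure
#' @param v named (or ordered) parameter vector of length 55
#' @return the updated \code{fg_model}
#' @export
vector_to_params <- function(model, v) {
  stopifnot(length(v) == 55)
  if (!is.null(names(v))) v <- v[param_names()]
  g <- model$gait
  g$phi0_s <- v[1]; g$cd_s <- v[2]; g$cv_s <- v[3]
  g$phi0_f <- v[4]; g$cd_f <- v[5]; g$cv_f <- v[6]
  g$early_tgt <- unname(v[7:10])
  g$late_knee <- v[11]; g$late_ankle <- v[12]; g$T_late <- v[13]
  g$T_early_p <- v[14]
  g$g1_vas <- v[15]; g$g1_sol <- v[16]; g$g1_gas <- v[17]
  g$ko_phi <- v[18]; g$ko_vas <- v[19]; g$ko_bfsh <- v[20]
  g$gp_s <- v[21]; g$gd_s <- v[22]; g$th_ref_s <- v[23]
  g$gp_f <- v[24]; g$gd_f <- v[25]; g$g4 <- v[26]
  g$g_ta <- v[27]; g$gsup_ta <- v[28]
  grp <- default_reflex()$groups
  r <- model$reflex
  r$kl <- stats::setNames(unname(v[29:37]), grp)
  r$kv <- stats::setNames(unname(v[38:46]), grp)
  r$h <- stats::setNames(unname(v[47:55]), grp)
  g <- lapply(g, unname)
  fg_model(body = model$body, muscles = model$muscles, reflex = r, gait = g,
           params = NULL)
}

#' Optimization bounds for the free parameters
#'
#' @return matrix with columns \code{lower} and \code{upper}, one row per
#'   parameter
#' @export
param_bounds <- function() {
  nm <- param_names()
  lo <- stats::setNames(numeric(55), nm)
  hi <- stats::setNames(numeric(55), nm)
  set <- function(names, l, u) {
    lo[names] <<- l
    hi[names] <<- u
  }
  set(c("phi0_s"), 0.1, 0.7)
  set(c("cd_s", "cd_f"), 0, 4)
  set(c("cv_s", "cv_f"), 0, 1.5)
  set("phi0_f", -0.1, 0.25)
  set("early_hip", 0.2, 1.2)
  set("early_roll", -0.2, 0.2)
  set("early_knee", 0.5, 2.0)
  set("early_ankle", -0.3, 0.4)
  set("late_knee", 0.02, 0.6)
  set("late_ankle", -0.3, 0.3)
  set("T_late", 0.2, 0.6)
  set("T_early_p", 0.15, 0.6)
  set(c("g1_vas", "g1_sol", "g1_gas"), 0, 4)
  set("ko_phi", 0.05, 0.6)
  set(c("ko_vas", "ko_bfsh"), 0, 6)
  set(c("gp_s", "gp_f"), 0, 10)
  set(c("gd_s", "gd_f"), 0, 3)
  set("th_ref_s", 0.03, 0.25)
  set("g4", 0, 3)
  set("g_ta", 0, 4)
  set("gsup_ta", 0, 4)
  set(paste0("kl_", default_reflex()$groups), 0.5, 8)
  set(paste0("kv_", default_reflex()$groups), 0.005, 0.2)
  set(paste0("h_", default_reflex()$groups), 0, 2)
  cbind(lower = lo, upper = hi)
}
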