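#' Tuned controller parameters
#'
#' The 55 free controller parameters shipped with the package: the best
#' point of the package's own CMA-ES tuning runs against the walking
#' cost, verified on long unperturbed walks.  \code{fg_model()} applies
#' them by default; pass \code{params = NULL} to get the untuned
#' structural defaults.
#'
#' @return named numeric vector of length 55
#' @export
shipped_params <- function() {
  c(
    phi0_s = 0.198097,
    cd_s = 1.090185,
    cv_s = 0.270434,
    phi0_f = -0.043745,
    cd_f = 1.114462,
    cv_f = 0.661934,
    early_hip = 1.075883,
    early_roll = -0.008038,
    early_knee = 1.648691,
    early_ankle = 0.031903,
    late_knee = 0.485691,
    late_ankle = 0.064797,
    T_late = 0.201144,
    T_early_p = 0.439809,
    g1_vas = 2.877258,
    g1_sol = 1.106522,
    g1_gas = 1.135592,
    ko_phi = 0.265440,
    ko_vas = 5.639427,
    ko_bfsh = 1.000000,
    gp_s = 3.240477,
    gd_s = 0.505035,
    th_ref_s = 0.131987,
    gp_f = 9.128966,
    gd_f = 0.977076,
    g4 = 1.388194,
    g_ta = 1.500000,
    gsup_ta = 1.200000,
    kl_HFL = 0.800000,
    kl_GLU = 0.800000,
    kl_HAM = 0.800000,
    kl_RF = 0.800000,
    kl_VAS = 0.800000,
    kl_BFSH = 0.800000,
    kl_PF = 0.800000,
    kl_TA = 1.600000,
    kl_ROLL = 0.800000,
    kv_HFL = 0.020000,
    kv_GLU = 0.020000,
    kv_HAM = 0.040000,
    kv_RF = 0.020000,
    kv_VAS = 0.050000,
    kv_BFSH = 0.050000,
    kv_PF = 0.020000,
    kv_TA = 0.020000,
    kv_ROLL = 0.050000,
    h_HFL = 0.500000,
    h_GLU = 0.500000,
    h_HAM = 0.500000,
    h_RF = 0.500000,
    h_VAS = 0.500000,
    h_BFSH = 0.500000,
    h_PF = 0.500000,
    h_TA = 0.500000,
    h_ROLL = 0.500000
  )
}
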