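#' Default muscle-tendon parameter table
#'
#' The 22 Hill-type MTUs of the model: per leg, nine pitch-joint muscles
#' (hip flexors HFL, glutei GLU, hamstrings HAM, rectus femoris RF, vasti
#' VAS, biceps femoris short head BFSH, gastrocnemius GAS, soleus SOL,
#' tibialis anterior TA) and two roll-joint muscles (hip abductors HAB,
#' adductors HAD).  HAM, RF and GAS are biarticular.
#'
#' Parameter values are adopted defaults in the tradition of reflex-based
#' walking models, scaled so that each muscle's contractile element stays
#' within its force-length operating range over the joint range of motion
#' (the virtual-work identity between MTU length and moment arms is exact,
#' see \code{\link{muscle_geometry}}).  Columns:
#' \describe{
#'   \item{name, leg}{muscle id and side (0 left, 1 right)}
#'   \item{Fmax}{maximum isometric force, N}
#'   \item{lopt, lslack}{optimal CE length and SE slack length, m}
#'   \item{vmax}{maximum shortening velocity, m/s}
#'   \item{w}{force-length width as a fraction of lopt}
#'   \item{fvN, fvK}{eccentric force plateau and force-velocity curvature}
#'   \item{epsref}{SE strain at Fmax}
#'   \item{tauA}{activation time constant, s}
#'   \item{dof1, dof2}{spanned leg DoFs (0 hip pitch, 1 hip roll, 2 knee,
#'     3 ankle; -1 if unused)}
#'   \item{r1, r2}{peak moment arm, m}
#'   \item{thmax1, thmax2}{joint angle of peak arm for cosine-saturating
#'     arms; NA for constant arms}
#'   \item{thref1, thref2}{reference angle at which the attachment
#'     contributes zero length change}
#'   \item{sgn1, sgn2}{+1 if muscle force drives the DoF positive}
#' }
#'
#' @return a data.frame with 22 rows of class \code{fg_muscles}
#' @export
default_muscles <- function() {
  one_leg <- data.frame(
    name  = c("HFL", "GLU", "HAM", "RF", "VAS", "BFSH", "GAS", "SOL", "TA",
              "HAB", "HAD"),
    Fmax  = c(2000, 1500, 3000, 1200, 6000, 800, 1500, 4000, 1200, 3000, 4500),
    lopt  = c(0.15, 0.15, 0.18, 0.16, 0.11, 0.11, 0.12, 0.08, 0.07, 0.08, 0.08),
    lslack = c(0.10, 0.13, 0.30, 0.34, 0.23, 0.16, 0.38, 0.25, 0.22, 0.07, 0.12),
    w     = c(0.8, 0.8, 1.0, 1.0, 0.7, 0.7, 1.0, 0.65, 0.6, 0.5, 0.4),
    ndof  = c(1, 1, 2, 2, 1, 1, 2, 1, 1, 1, 1),
    dof1  = c(0, 0, 0, 0, 2, 2, 2, 3, 3, 1, 1),
    r1    = c(0.08, 0.08, 0.07, 0.05, 0.055, 0.04, 0.015, 0.05, 0.04,
              0.06, 0.04),
    thmax1 = c(NA, NA, NA, NA, 0.8, NA, NA, -0.2, 0.2, NA, NA),
    thref1 = c(0.7, 0.7, 0.7, 0.7, 1.31, 1.31, 1.31, -0.1, -0.1, 0, 0),
    sgn1  = c(1, -1, -1, 1, -1, 1, 1, -1, 1, -1, 1),
    dof2  = c(-1, -1, 2, 2, -1, -1, 3, -1, -1, -1, -1),
    r2    = c(0, 0, 0.04, 0.05, 0, 0, 0.05, 0, 0, 0, 0),
    thmax2 = c(NA, NA, NA, 0.8, NA, NA, -0.2, NA, NA, NA, NA),
    thref2 = c(0, 0, 1.31, 1.31, 0, 0, -0.1, 0, 0, 0, 0),
    sgn2  = c(1, 1, 1, -1, 1, 1, -1, 1, 1, 1, 1)
  )
  m <- rbind(cbind(one_leg, leg = 0L), cbind(one_leg, leg = 1L))
  m$name <- paste0(m$name, "_", ifelse(m$leg == 0, "L", "R"))
  m$vmax <- 12 * m$lopt
  m$fvN <- 1.5
  m$fvK <- 5
  m$epsref <- 0.04
  m$tauA <- 0.01
  rownames(m) <- m$name
  stopifnot(all(m$Fmax > 0), all(m$tauA > 0))
  class(m) <- c("fg_muscles", "data.frame")
  m
}

# internal: data.frame -> plain list of columns for the C++ core
mtbl_list <- function(muscles) {
  m <- as.data.frame(muscles)
  lapply(m[c("leg", "ndof", "dof1", "dof2", "Fmax", "lopt", "lslack", "vmax",
             "w", "fvN", "fvK", "epsref", "tauA", "r1", "thmax1", "thref1",
             "sgn1", "r2", "thmax2", "thref2", "sgn2")], function(x) {
               if (is.integer(x)) x else as.numeric(x)
             })
}

#' Muscle-tendon unit forces
#'
#' Contractile, parallel, buffer and total MTU force at a given CE length,
#' CE velocity and activation: \code{F_ce = A Fmax f_l(l_ce) f_v(v_ce)},
#' \code{F_mtu = F_ce + F_pe - F_be}, floored at zero (muscles cannot push).
#'
#' @param muscles an \code{fg_muscles} table
#' @param i muscle index (row) or name
#' @param l_ce CE length, m
#' @param v_ce CE velocity, m/s (negative = shortening)
#' @param A activation in [0, 1]
#' @return list with F_ce, F_pe, F_be, F_mtu, f_l, f_v
#' @export
mtu_force <- function(muscles, i, l_ce, v_ce = 0, A = 0) {
  if (is.character(i)) i <- match(i, muscles$name)
  stopifnot(is.finite(l_ce), is.finite(v_ce), A >= 0, A <= 1)
  cpp_mtu_force(mtbl_list(muscles), as.integer(i), l_ce, v_ce, A)
}

#' First-order activation dynamics
#'
#' Discretized \code{dA/dt = (S - A) / tau_A}: muscle activation is a
#' low-pass filtered copy of the neural stimulation.
#'
#' @param A current activation
#' @param S stimulation in [0, 1]
#' @param dt time step, s
#' @param tau_A activation time constant, s
#' @export
activation_step <- function(A, S, dt, tau_A) {
  stopifnot(all(S >= 0), all(S <= 1), dt > 0, tau_A > 0)
  A1 <- A + dt * (S - A) / tau_A
  pmin(pmax(A1, 0), 1)
}

#' Muscle geometry: MTU lengths and moment-arm matrix
#'
#' MTU length as a function of the spanned joint angles and the 14 x 22
#' moment-arm matrix C(theta).  Arms are constant or cosine-saturating in
#' the joint angle; the matrix is the exact negative gradient of the MTU
#' lengths, so d l_mtu / d theta_j = -C[j, m] holds to machine precision.
#'
#' @param muscles an \code{fg_muscles} table
#' @param theta 14-vector of generalized coordinates
#' @return list with \code{l_mtu} (length 22) and \code{C} (14 x 22)
#' @export
muscle_geometry <- function(muscles, theta) {
  g <- cpp_mtu_geometry(mtbl_list(muscles), theta)
  colnames(g$C) <- muscles$name
  names(g$lmtu) <- muscles$name
  list(l_mtu = g$lmtu, C = g$C)
}

#' Joint torques from muscle forces
#'
#' \code{tau = C F}.  Muscle forces must be non-negative; the free-body
#' trunk rows of C are structurally zero.
#'
#' @param C 14 x n moment-arm matrix
#' @param F n-vector of tensile muscle forces, N
#' @export
torques_from_forces <- function(C, F) {
  if (any(F < -1e-9)) stop("muscle forces must be non-negative")
  drop(C %*% F)
}

#' Hill force-length and force-velocity factors for all muscles
#'
#' @param muscles an \code{fg_muscles} table
#' @param l_ce,v_ce vectors of CE lengths and velocities (length 22)
#' @return matrix with columns f_l, f_v
#' @export
muscle_curves <- function(muscles, l_ce, v_ce) {
  out <- cpp_muscle_curves(mtbl_list(muscles), l_ce, v_ce)
  colnames(out) <- c("f_l", "f_v")
  rownames(out) <- muscles$name
  out
}
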