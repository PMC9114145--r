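#' Walking cost function
#'
#' Two-stage cost for gait-parameter tuning: candidates that fall score
#' \code{2 c0 - x_fall} (walking farther before the fall is better), and
#' candidates that keep walking score \code{c0 + d_steady}, where the
#' steadiness measure d_steady sums, over the last three left heel-strikes,
#' the changes in the relative Cartesian limb positions between successive
#' heel-strikes (Euclidean norms per limb; a perfectly periodic gait gives
#' 0).  d_steady is capped at c0 so every falling candidate scores strictly
#' worse than every non-falling one.  c0 = 1000.
#'
#' @param model an \code{fg_model}
#' @param duration simulation time, s
#' @param c0 normalization constant
#' @param ... passed to \code{\link{simulate_walk}}
#' @return list with J, fell, x_fall, d_steady and the number of heel
#'   strikes
#' @export
evaluate_cost <- function(model, duration = 12, c0 = 1000, ...) {
  w <- tryCatch(simulate_walk(model, duration = duration, log_every = 50L,
                              ...),
                error = function(e) NULL)
  if (is.null(w)) {
    # simulation blow-up counts as a fall at the origin
    return(list(J = 2 * c0, fell = TRUE, x_fall = 0, d_steady = NA,
                n_heel_strikes = 0L))
  }
  nhs <- nrow(w$heel_strikes)
  if (w$fell) {
    x <- max(w$x_fall, 0)
    return(list(J = 2 * c0 - x, fell = TRUE, x_fall = w$x_fall,
                d_steady = w$d_steady, n_heel_strikes = nhs))
  }
  d <- w$d_steady
  if (!is.finite(d)) d <- c0  # too few strides to assess steadiness
  d <- min(d, c0)
  list(J = c0 + d, fell = FALSE, x_fall = NA, d_steady = d,
       n_heel_strikes = nhs)
}

#' Covariance matrix adaptation evolution strategy
#'
#' Standard (mu/mu_w, lambda)-CMA-ES minimizer with rank-mu update,
#' cumulative step-size adaptation and box constraints handled by repair
#' plus a quadratic out-of-bounds penalty.  Deterministic for a fixed seed.
#'
#' @param fn objective function of a numeric vector
#' @param x0 initial point
#' @param sigma0 initial step size
#' @param lower,upper box bounds (recycled)
#' @param budget maximum number of function evaluations
#' @param lambda population size (default 4 + floor(3 log n))
#' @param seed RNG seed
#' @param target stop early when the best value falls below this
#' @param trace print progress every \code{trace} generations (0 = silent)
#' @return list with \code{par} (best point), \code{value}, \code{history}
#'   (per-generation best), \code{evals}
#' @export
cmaes <- function(fn, x0, sigma0 = 0.3, lower = -Inf, upper = Inf,
                  budget = 5000, lambda = NULL, seed = 1,
                  target = -Inf, trace = 0) {
  set.seed(seed)
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  wts <- log(mu + 0.5) - log(seq_len(mu))
  wts <- wts / sum(wts)
  mueff <- 1 / sum(wts^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  B <- diag(n)
  D <- rep(1, n)
  C <- diag(n)
  invsqrtC <- diag(n)
  eigen_age <- 0

  best <- list(par = xmean, value = Inf)
  evals <- 0
  gen <- 0
  hist <- numeric(0)

  while (evals + lambda <= budget) {
    gen <- gen + 1
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)
    X <- xmean + sigma * Y
    f <- numeric(lambda)
    for (k in seq_len(lambda)) {
      xk <- X[, k]
      xr <- pmin(pmax(xk, lower), upper)
      pen <- sum((xk - xr)^2)
      f[k] <- fn(xr) + 1e6 * pen
      evals <- evals + 1
      if (f[k] < best$value) best <- list(par = xr, value = f[k])
    }
    ord <- order(f)
    hist <- c(hist, f[ord[1]])
    sel <- ord[seq_len(mu)]
    yw <- drop(Y[, sel, drop = FALSE] %*% wts)
    xmean <- xmean + sigma * yw

    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * evals / lambda)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    artmp <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (wts * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    if (evals - eigen_age > lambda / (c1 + cmu) / n / 10) {
      eigen_age <- evals
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
      invsqrtC <- B %*% (t(B) / D)
    }
    if (trace > 0 && gen %% trace == 0) {
      message(sprintf("gen %d evals %d best %.4f sigma %.3g", gen, evals,
                      best$value, sigma))
    }
    if (best$value <= target) break
  }
  list(par = best$par, value = best$value, history = hist, evals = evals)
}

#' Tune gait parameters by CMA-ES
#'
#' Minimizes the walking cost over (a subset of) the 55 free controller
#' parameters.  The search runs in box-normalized coordinates with the
#' bounds of \code{\link{param_bounds}}.
#'
#' @param model starting \code{fg_model}
#' @param params names of parameters to tune (default: all 55)
#' @param duration simulated walking time per evaluation, s
#' @param budget maximum cost evaluations
#' @param seed RNG seed
#' @param sigma0 initial step size in normalized coordinates
#' @param trace progress printing interval (generations)
#' @param ... passed to \code{\link{evaluate_cost}}
#' @return list with the tuned \code{model}, best parameter \code{vector},
#'   best \code{value} and optimization \code{history}
#' @export
optimize_gait <- function(model, params = param_names(), duration = 12,
                          budget = 2000, seed = 1, sigma0 = 0.12,
                          trace = 0, ...) {
  v0 <- params_to_vector(model)
  bounds <- param_bounds()
  idx <- match(params, rownames(bounds))
  stopifnot(!anyNA(idx))
  lo <- bounds[idx, "lower"]
  hi <- bounds[idx, "upper"]
  z0 <- (unname(v0[params]) - lo) / (hi - lo)
  obj <- function(z) {
    v <- v0
    v[params] <- lo + z * (hi - lo)
    m <- vector_to_params(model, v)
    evaluate_cost(m, duration = duration, ...)$J
  }
  res <- cmaes(obj, z0, sigma0 = sigma0, lower = 0, upper = 1,
               budget = budget, seed = seed, trace = trace)
  vbest <- v0
  vbest[params] <- lo + res$par * (hi - lo)
  list(model = vector_to_params(model, vbest), vector = vbest,
       value = res$value, history = res$history, evals = res$evals)
}
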