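# shared fixtures, built once per test run

fg_test_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- fg_model()
    m
  }
})

# body config reduced to a single point-mass pendulum at the left hip:
# thigh carries a point mass at distance l, everything distal is massless
pendulum_body <- function(m = 1, l = 0.46, gravity = 9.81) {
  b <- default_body(gravity = gravity)
  b$thigh$mass <- m
  b$thigh$com_offset <- l
  b$thigh$I <- c(1e-9, 1e-9, 1e-9)
  b$shank$mass <- 0
  b$shank$I <- c(0, 0, 0)
  b$foot$mass <- 0
  b$foot$I <- c(0, 0, 0)
  b$limits$k <- 0
  b$limits$d <- 0
  b
}

# configuration with the trunk high above ground (no contact), legs posed
airborne_theta <- function(q_left = c(0.3, 0, 0.3, 0),
                           q_right = c(0.3, 0, 0.3, 0)) {
  q <- rep(0, 14)
  q[3] <- 2
  q[7:10] <- q_left
  q[11:14] <- q_right
  q
}

# exact non-negative least squares by active-set enumeration (oracle for
# small force-distribution problems): minimizes |C f - tau| over f >= 0
nnls_enum <- function(C, tau) {
  n <- ncol(C)
  best <- NULL
  bestval <- Inf
  for (k in 0:(2^n - 1)) {
    act <- which(bitwAnd(k, 2^(seq_len(n) - 1)) > 0)  # free variables
    f <- numeric(n)
    if (length(act) > 0) {
      Cs <- C[, act, drop = FALSE]
      fs <- tryCatch(qr.solve(Cs, tau), error = function(e) NULL)
      if (is.null(fs)) {
        fs <- drop(MASS::ginv(Cs) %*% tau)
      }
      if (any(fs < -1e-10)) next
      f[act] <- pmax(fs, 0)
    }
    v <- sum((drop(C %*% f) - tau)^2)
    if (v < bestval - 1e-12) {
      bestval <- v
      best <- f
    }
  }
  list(F = best, value = bestval)
}
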