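test_that("planned accelerations map to static gravity torques at rest", {
  b <- default_body()
  th <- airborne_theta(c(0.4, 0.05, 0.5, -0.1))
  tau <- accel_to_torques(b, rep(0, 4), th, rep(0, 14), leg = "left")
  # statics oracle: pure gravitational torque of the hanging leg
  tau_g <- inverse_dynamics(b, th, rep(0, 14), rep(0, 14))
  expect_equal(tau, tau_g[7:10], tolerance = 1e-10)
})

test_that("swing torque extraction matches the full equation of motion", {
  b <- default_body()
  set.seed(9)
  th <- airborne_theta(runif(4, 0, 1), runif(4, 0, 1))
  thd <- rnorm(14, 0, 0.5)
  acc <- rnorm(4, 0, 5)
  tau <- accel_to_torques(b, acc, th, thd, leg = "right")
  qdd <- rep(0, 14)
  qdd[11:14] <- acc
  expect_equal(tau, inverse_dynamics(b, th, thd, qdd)[11:14])
})

test_that("two-muscle antagonist pair distributes like exact NNLS", {
  C <- matrix(c(0.05, -0.05), 1, 2)
  r <- distribute_forces(C, 2, iterations = 7)
  expect_equal(r$F[1], 2 / 0.05, tolerance = 0.05)
  expect_equal(r$F[2], 0, tolerance = 1e-6)
  # zero torque distributes zero force
  r0 <- distribute_forces(C, 0)
  expect_equal(r0$F, c(0, 0))
  expect_equal(r0$residual, 0)
})

test_that("distribution is non-negative and matches an enumerated NNLS oracle", {
  # oracle comparison on the model's own sagittal moment-arm geometry
  # (one leg's nine pitch-joint muscles acting on hip, knee, ankle) with
  # stepping-scale torques
  m <- fg_test_model()
  set.seed(10)
  pitch_idx <- which(m$muscles$leg == 0)[1:9]
  for (rep in 1:12) {
    q <- airborne_theta(c(runif(1, 0, 0.8), 0, runif(1, 0.2, 1.2),
                          runif(1, -0.3, 0.3)))
    Cb <- muscle_geometry(m$muscles, q)$C[c(7, 9, 10), pitch_idx]
    tau <- c(rnorm(1, 0, 25), rnorm(1, 0, 12), rnorm(1, 0, 6))
    r <- distribute_forces(Cb, tau, iterations = 7)
    expect_true(all(r$F >= -1e-12))
    oracle <- nnls_enum(Cb, tau)
    oracle_res <- abs(drop(Cb %*% oracle$F) - tau)
    # per-joint residual within the documented 3 N of the exact
    # non-negative optimum
    expect_true(all(abs(r$residual) <= oracle_res + 3))
  }
  # and on generic random instances the result is always non-negative
  for (rep in 1:50) {
    C <- matrix(runif(2 * 5, -0.08, 0.08), 2, 5)
    r <- distribute_forces(C, rnorm(2, 0, 5), iterations = 7)
    expect_true(all(r$F >= -1e-12))
  }
})

test_that("residual negative force shrinks monotonically over iterations", {
  set.seed(11)
  m <- fg_test_model()
  g <- muscle_geometry(m$muscles, airborne_theta(c(0.4, 0, 0.6, 0)))
  C <- g$C[7:10, 1:11]
  for (rep in 1:200) {
    tau <- rnorm(4, 0, 20)
    res_prev <- Inf
    for (it in 1:7) {
      r <- distribute_forces(C, tau, iterations = it)
      res <- sqrt(sum(r$residual^2))
      expect_lte(res, res_prev + 1e-9)
      res_prev <- res
    }
  }
})

test_that("inverse muscle model inverts the contractile force law", {
  mus <- default_muscles()
  i <- match("GLU_L", mus$name)
  # F = Fmax at the optimum demands full stimulation
  S <- forces_to_stimulation(mus[i, ], mus$Fmax[i], mus$lopt[i], 0)
  expect_equal(S, 1)
  expect_equal(forces_to_stimulation(mus[i, ], 0, mus$lopt[i], 0), 0)
  # scaling f_v scales the stimulation inversely before clamping
  S1 <- forces_to_stimulation(mus[i, ], 300, mus$lopt[i], 0)
  v <- -0.25 * mus$vmax[i]
  fv <- mtu_force(mus, i, mus$lopt[i], v, 1)$f_v
  S2 <- forces_to_stimulation(mus[i, ], 300, mus$lopt[i], v)
  expect_equal(S2 / S1, 1 / fv, tolerance = 1e-6)
  # the denominator floor keeps stimulations finite at the force limits
  S3 <- forces_to_stimulation(mus[i, ], 100, 2 * mus$lopt[i], 0)
  expect_lte(S3, 1)
  expect_error(forces_to_stimulation(mus[i, ], -5, mus$lopt[i], 0))
})

test_that("force distribution residual stays below 3 N per joint for a step-like movement", {
  # representative planned stepping movement on the trunk-fixed leg:
  # toe-off configuration through mid-swing to heel-strike
  m <- fg_test_model()
  goals <- rbind(c(0.6, 0.0, 1.2, 0.1, 0.3),   # mid-swing flexion
                 c(0.45, 0.0, 0.15, 0.05, 0.4)) # heel-strike extension
  sw <- simulate_swing(m, goals, leg = "left",
                       q0_leg = c(-0.15, 0.0, 0.25, -0.1), settle = 0.4)
  sel <- sw$t >= sw$settle
  rmse <- sqrt(colMeans(sw$resid[sel, ]^2))
  expect_true(all(rmse < 3))
})
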