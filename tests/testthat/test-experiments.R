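test_that("NRMSE metric: identity, offset scaling and brute-force oracle", {
  x <- sin(seq(0, 5, by = 0.01))
  expect_equal(compute_nrmse(x, x, 2), 0)
  expect_equal(compute_nrmse(x + 2, x, 2), 1)
  set.seed(12)
  a <- rnorm(500)
  b <- rnorm(500)
  brute <- sqrt(sum((a - b)^2) / 500) / 1.7
  expect_equal(compute_nrmse(a, b, 1.7), brute)
  expect_error(compute_nrmse(a, b, 0))
  expect_error(compute_nrmse(a, b[-1], 1))
})

test_that("inverse kinematics recovers forward-kinematics targets", {
  b <- default_body()
  set.seed(13)
  for (rep in 1:10) {
    q <- c(runif(1, 0, 1), runif(1, -0.2, 0.2), runif(1, 0.2, 1.2),
           runif(1, -0.3, 0.3))
    target <- flexgait:::ankle_position(b, q)
    ik <- leg_ik(b, target, q0_leg = c(0.3, 0, 0.6, 0))
    expect_true(ik$converged)
    expect_lt(ik$err, 1e-4)
  }
})

test_that("center-out fixture spans the intended workspace", {
  b <- default_body()
  co <- center_out_targets(b)
  expect_equal(nrow(co$targets), 12)
  d <- sqrt(rowSums(sweep(co$targets, 2, co$center)^2))
  expect_true(all(d > 0.15 & d < 0.65))
  expect_gt(max(d) - min(d), 0.25)  # covers a large portion of the workspace
})

test_that("random reach targets respect the 15-85% range and slack exclusion", {
  m <- fg_test_model()
  lo <- m$body$limits$lo
  hi <- m$body$limits$hi
  set.seed(14)
  mus <- m$muscles[m$muscles$leg == 0, ]
  for (rep in 1:25) {
    q <- flexgait:::draw_target(m, "left")
    frac <- (q - lo) / (hi - lo)
    expect_true(all(frac >= 0.15 - 1e-9 & frac <= 0.85 + 1e-9))
    qf <- rep(0, 14)
    qf[7:10] <- q
    lm <- muscle_geometry(m$muscles, qf)$l_mtu[rownames(mus)]
    expect_true(all(lm - mus$lslack > 0.4 * mus$lopt))
  }
})

test_that("reach experiments are reproducible bit-for-bit under a seed", {
  m <- fg_test_model()
  r1 <- run_random_reaches(m, times = c(0.4), n_per_time = 2, seed = 99)
  r2 <- run_random_reaches(m, times = c(0.4), n_per_time = 2, seed = 99)
  expect_identical(r1$mean_nrmse, r2$mean_nrmse)
  expect_identical(r1$raw, r2$raw)
})

test_that("walking summary metrics are internally consistent", {
  m <- fg_test_model()
  rw <- run_walk(m, duration = 4, discard_steps = 1, log_every = 20L)
  w <- rw$walk
  # speed definition: displacement over time after the discarded steps
  if (!is.na(rw$speed)) {
    hs <- w$heel_strikes
    t0 <- hs[2, "t"]
    i0 <- which.min(abs(w$t - t0))
    n <- nrow(w$q)
    expect_equal(rw$speed,
                 (w$q[n, "x"] - w$q[i0, "x"]) / (w$t[n] - t0))
  }
  # vertical ground reaction forces are never negative
  expect_true(all(w$grf[, c("L_fz", "R_fz")] >= 0))
  # phases are always valid codes and stance alternates with swing
  expect_true(all(w$phase %in% 0:2))
})

test_that("walking is deterministic given identical inputs", {
  m <- fg_test_model()
  w1 <- simulate_walk(m, duration = 1.5, log_every = 50L)
  w2 <- simulate_walk(m, duration = 1.5, log_every = 50L)
  expect_identical(w1$q, w2$q)
  expect_identical(w1$heel_strikes, w2$heel_strikes)
})

test_that("stimulations stay within bounds throughout a walk", {
  m <- fg_test_model()
  w <- simulate_walk(m, duration = 2, log_stims = TRUE, log_every = 20L)
  expect_true(all(w$S >= 0.01 - 1e-9 & w$S <= 1 + 1e-9))
})

test_that("muscle tables round-trip through the CSV schema", {
  p <- tempfile(fileext = ".csv")
  write_muscle_table(default_muscles(), p)
  m2 <- read_muscle_table(p)
  expect_s3_class(m2, "fg_muscles")
  expect_equal(m2$Fmax, default_muscles()$Fmax)
  expect_equal(m2$r1, default_muscles()$r1)
  # the shipped copy matches the in-code defaults
  shipped <- system.file("extdata", "muscles_default.csv",
                         package = "flexgait")
  expect_equal(read_muscle_table(shipped)$lopt, default_muscles()$lopt)
})

test_that("parameter vectors round-trip through JSON", {
  skip_if_not_installed("jsonlite")
  m <- fg_test_model()
  p <- tempfile(fileext = ".json")
  write_params_json(m, p)
  m2 <- read_params_json(p, base = m)
  expect_equal(params_to_vector(m2), params_to_vector(m))
})
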