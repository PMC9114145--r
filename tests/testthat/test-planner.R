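test_that("finite state machine follows the gait phase cycle", {
  # stance -> early swing on contralateral contact
  r <- fsm_update("stance", 0, 1.0, ipsi_contact = TRUE,
                  contra_contact = TRUE)
  expect_equal(r$phase, "early_swing")
  expect_true(r$transitioned)
  # early swing -> late swing after exactly the 0.3 s timer
  r <- fsm_update("early_swing", 1.0, 1.29, FALSE, FALSE)
  expect_equal(r$phase, "early_swing")
  r <- fsm_update("early_swing", 1.0, 1.30, FALSE, FALSE)
  expect_equal(r$phase, "late_swing")
  # late swing holds until ipsilateral contact
  r <- fsm_update("late_swing", 1.3, 2.5, FALSE, TRUE)
  expect_equal(r$phase, "late_swing")
  r <- fsm_update("late_swing", 1.3, 2.5, TRUE, FALSE)
  expect_equal(r$phase, "stance")
  # no invalid shortcuts: stance never jumps straight to late swing and
  # contact during early swing does not truncate the timer
  r <- fsm_update("stance", 0, 1, FALSE, FALSE)
  expect_equal(r$phase, "stance")
  r <- fsm_update("early_swing", 1.0, 1.1, TRUE, TRUE)
  expect_equal(r$phase, "early_swing")
})

test_that("rest-to-rest minimum-jerk plan is the classic quintic", {
  a <- minjerk_coeffs(c(0, 0, 0), c(1, 0, 0), 1)
  expect_equal(a, c(0, 0, 0, 10, -15, 6), tolerance = 1e-10)
  # constant plan when start equals goal
  a <- minjerk_coeffs(c(0.7, 0, 0), c(0.7, 0, 0), 0.5)
  tr <- minjerk_eval(a, seq(0, 0.5, by = 0.01))
  expect_true(all(abs(tr[, "x"] - 0.7) < 1e-12))
  expect_error(minjerk_coeffs(c(0, 0, 0), c(1, 0, 0), 0))
})

test_that("quintic satisfies arbitrary boundary conditions", {
  set.seed(7)
  for (rep in 1:200) {
    X0 <- rnorm(3)
    X1 <- rnorm(3)
    T <- runif(1, 0.1, 2)
    a <- minjerk_coeffs(X0, X1, T)
    s0 <- minjerk_eval(a, 0)
    s1 <- minjerk_eval(a, T)
    expect_lt(max(abs(s0 - X0)), 1e-10)
    expect_lt(max(abs(s1 - X1)), 1e-8 * max(1, max(abs(X1))))
  }
})

test_that("replanning from an on-plan state reproduces the plan", {
  set.seed(8)
  for (rep in 1:100) {
    X0 <- rnorm(3)
    X1 <- c(rnorm(1), 0, 0)
    T <- runif(1, 0.4, 1.5)
    a <- minjerk_coeffs(X0, X1, T)
    t1 <- runif(1, 0.05, T - 0.05)
    s <- minjerk_eval(a, t1)
    a2 <- minjerk_coeffs(s, X1, T - t1)
    tt <- seq(0, T - t1, length.out = 20)
    expect_lt(max(abs(minjerk_eval(a2, tt)[, "x"] -
                        minjerk_eval(a, t1 + tt)[, "x"])), 1e-7)
  }
})

test_that("replan_acceleration freezes below the 0.03 s window", {
  a <- minjerk_coeffs(c(0, 0, 0), c(1, 0, 0), 1)
  r <- replan_acceleration(c(0.1, 0.3, 0.2), c(1, 0, 0), t_remaining = 0.5)
  expect_false(r$frozen)
  rf <- replan_acceleration(c(0.9, 0.1, 0), c(1, 0, 0), t_remaining = 0.02,
                            frozen_coeffs = a, t_since_freeze = 0.95)
  expect_true(rf$frozen)
  # the frozen answer comes from the stored plan, not a new one
  expect_equal(rf$coeffs, a)
  expect_error(replan_acceleration(c(0, 0, 0), c(1, 0, 0), 0.01))
})

test_that("balance law: offset, linearity and trunk cancellation", {
  # zero gains: target is the constant offset
  expect_equal(balance_targets(0.3, 0.1, 0, phi0 = 0.2, c_d = 0, c_v = 0),
               0.2)
  # linear in the displacement
  d1 <- balance_targets(0.1, 0, 0, 0, 1.5, 0)
  d2 <- balance_targets(0.2, 0, 0, 0, 1.5, 0)
  expect_equal(d2, 2 * d1)
  # trunk orientation equal to the thigh target cancels exactly
  expect_equal(balance_targets(0, 0, 0.2, phi0 = 0.2, c_d = 1, c_v = 1), 0)
})

test_that("obstacle retargeting is linear in the obstacle size", {
  nom <- c(0.6, 0, 1.2, 0.1)
  t0 <- obstacle_targets(0, "sagittal", nominal = nom)
  expect_equal(t0, nom)
  t1 <- obstacle_targets(0.1, "sagittal", nominal = nom, margin = 0)
  t2 <- obstacle_targets(0.2, "sagittal", nominal = nom, margin = 0)
  expect_equal(t2 - nom, 2 * (t1 - nom), tolerance = 1e-12)
  # lateral policy adjusts only hip abduction
  tl <- obstacle_targets(0.1, "lateral", nominal = nom, margin = 0)
  expect_true(tl[2] != nom[2])
  expect_equal(tl[c(1, 3, 4)], nom[c(1, 3, 4)])
  # out-of-range targets clamp with a warning
  expect_warning(obstacle_targets(1.0, "sagittal", nominal = nom))
})

test_that("speed and direction commands", {
  g <- default_gait()
  g2 <- speed_command(g, 8)
  expect_equal(g2$th_ref_s, 8 * pi / 180)
  expect_identical(g2[names(g2) != "th_ref_s"], g[names(g) != "th_ref_s"])
  # direction: zero inside tolerance, sign flips with the error
  expect_equal(direction_command(0.02, 0, offset = 0.06, tol = 0.04), 0)
  expect_equal(direction_command(0.5, 0, offset = 0.06, tol = 0.04), 0.06)
  expect_equal(direction_command(-0.5, 0, offset = 0.06, tol = 0.04), -0.06)
})
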