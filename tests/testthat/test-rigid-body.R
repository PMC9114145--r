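test_that("mass matrix is symmetric positive definite across configurations", {
  b <- default_body()
  set.seed(1)
  for (i in 1:25) {
    q <- c(rnorm(3, 0, 0.5), runif(3, -0.5, 0.5), runif(8, -0.6, 1.2))
    M <- cpp_mass_matrix(unclass(b), q)
    expect_lt(max(abs(M - t(M))), 1e-9)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("equilibrium: zero gravity, zero torque, at rest gives zero acceleration", {
  b <- pendulum_body(gravity = 0)
  st <- body_state(airborne_theta(c(0.4, 0, 0, 0)))
  qdd <- forward_dynamics(b, st, active = 7)
  expect_lt(max(abs(qdd)), 1e-10)
})

test_that("small-angle pendulum oscillates at sqrt(g/l)", {
  b <- pendulum_body(m = 1, l = 0.46)
  st <- body_state(airborne_theta(c(0.01, 0, 0, 0)))
  dt <- 1e-4
  n <- 30000
  th <- numeric(n)
  conf <- unclass(b)
  q <- st$theta
  qd <- st$theta_dot
  for (k in seq_len(n)) {
    qdd <- cpp_fwd_dyn(conf, q, qd, rep(0, 14), 7L, FALSE)
    qd <- qd + qdd * dt
    q <- q + qd * dt
    th[k] <- q[7]
  }
  zc <- which(diff(sign(th)) != 0)
  period <- 2 * mean(diff(zc)) * dt
  expect_equal(period, 2 * pi * sqrt(0.46 / 9.81), tolerance = 0.01)
})

test_that("inverse dynamics of a static pendulum is the gravity torque", {
  b <- pendulum_body(m = 2, l = 0.4)
  phi <- 0.6
  tau <- inverse_dynamics(b, airborne_theta(c(phi, 0, 0, 0)), rep(0, 14),
                          rep(0, 14))
  # hip flexion positive swings the leg forward; holding the deflected
  # pendulum takes m g l sin(phi)
  expect_equal(tau[7], 2 * 9.81 * 0.4 * sin(phi), tolerance = 1e-8)
})

test_that("forward then inverse dynamics recovers the torques to 1e-6", {
  b <- default_body()
  b$limits$k <- 0
  b$limits$d <- 0
  set.seed(2)
  for (i in 1:10) {
    q <- airborne_theta(runif(4, -0.2, 0.8), runif(4, -0.2, 0.8))
    qd <- rnorm(14, 0, 0.5)
    tau <- rnorm(14, 0, 10)
    tau[1:6] <- 0
    st <- body_state(q, qd)
    qdd <- forward_dynamics(b, st, tau)
    tau2 <- inverse_dynamics(b, q, qd, qdd)
    expect_lt(max(abs(tau2 - tau)), 1e-6)
  }
})

test_that("passive contact-free skeleton conserves energy to 0.1% over 5 s", {
  b <- default_body()
  b$limits$k <- 0
  b$limits$d <- 0
  q <- airborne_theta(c(0.8, 0.1, 0.3, 0.2), c(-0.4, -0.1, 0.5, -0.3))
  st <- body_state(q)
  E0 <- body_energy(b, st)
  st2 <- integrate_step(b, st, dt = 1e-4, n = 50000, active = 7:14)
  E1 <- body_energy(b, st2)
  expect_lt(abs(E1 - E0) / abs(E0), 1e-3)
})

test_that("contact points above ground produce no force", {
  b <- default_body()
  st <- body_state(airborne_theta())
  cf <- contact_forces(b, st)
  expect_true(all(cf$f_normal == 0))
  expect_true(all(cf$penetration <= 0))
})

test_that("static standing carries body weight on the contact springs", {
  b <- default_body()
  st <- standing_state(b)
  cf <- contact_forces(b, st)
  w <- 80 * 9.81
  expect_equal(sum(cf$f_normal), w, tolerance = 0.01 * w)
  expect_true(all(cf$f_normal >= 0))
})

test_that("sliding friction opposes slip and respects the cone", {
  b <- default_body()
  st <- standing_state(b)
  st$theta_dot[1] <- 0.3  # forward slide
  cf <- contact_forces(b, st)
  loaded <- cf$f_normal > 0
  expect_true(all(cf$f_tan_x[loaded] < 0))
  ft <- sqrt(cf$f_tan_x^2 + cf$f_tan_y^2)
  expect_true(all(ft <= b$contact$mu * cf$f_normal + 1e-9))
})

test_that("integrator is deterministic and converges with the step size", {
  b <- default_body()
  st <- body_state(airborne_theta(c(0.5, 0, 0.4, 0)))
  a <- integrate_step(b, st, dt = 1e-4, n = 10000, active = 7:10)
  b2 <- integrate_step(b, st, dt = 1e-4, n = 10000, active = 7:10)
  expect_identical(a$theta, b2$theta)
  c2 <- integrate_step(b, st, dt = 5e-5, n = 20000, active = 7:10)
  expect_lt(max(abs(a$theta[7:10] - c2$theta[7:10])), 1e-3)
})

test_that("segment masses sum to the body mass and zero state is valid", {
  b <- default_body()
  total <- b$trunk$mass + 2 * (b$thigh$mass + b$shank$mass + b$foot$mass)
  expect_equal(total, 80)
  expect_error(body_state(rep(NA, 14)))
})
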