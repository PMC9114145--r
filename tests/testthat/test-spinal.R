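test_that("stretch reflex: threshold point, rectification and clamping", {
  Kl <- 20
  Kv <- 1
  h <- 0.5
  # at the threshold the bracket is exactly zero -> baseline tone
  S <- stretch_reflex(l_ce = h / Kl, v_ce = 0, u = 0, u_dot = 0,
                      K_l = Kl, K_v = Kv, h = h, S_min = 0)
  expect_equal(S, 0)
  # negative bracket rectifies to zero
  expect_equal(stretch_reflex(0, 0, -1, 0, Kl, Kv, h, 0), 0)
  # large drive clamps at 1
  expect_equal(stretch_reflex(1, 0, 1, 0, Kl, Kv, h, 0), 1)
  # baseline tone floor
  expect_equal(stretch_reflex(0, 0, -1, 0, Kl, Kv, h, 0.01), 0.01)
})

test_that("delay line implements exact transport delay", {
  x <- sin(seq(0, 2, by = 0.01))
  expect_equal(delay_signal(x, 0, 0.01), x)
  expect_equal(delay_signal(rep(3, 50), 0.05, 0.01), rep(3, 50))
  step <- c(rep(0, 20), rep(1, 30))
  d <- delay_signal(step, 0.05, 0.01)
  expect_equal(d, c(rep(0, 25), rep(1, 25)))
  expect_error(delay_signal(x, 0.0123, 0.01))
})

test_that("reflex inversion identity: command reproduces the stimulation", {
  set.seed(5)
  mus <- default_muscles()
  ctrl <- default_ctrl(mus)
  for (rep in 1:1000) {
    i <- sample(22, 1)
    S_des <- runif(1)
    l_ce <- runif(1, 0.5, 1.5) * mus$lopt[i]
    u <- stimulation_to_command(S_des, l_ce, ctrl$Kl[i], ctrl$h[i])
    S <- stretch_reflex(l_ce, 0, u, 0, ctrl$Kl[i], ctrl$Kv[i], ctrl$h[i],
                        S_min = 0)
    expect_equal(S, min(max(S_des, 0), 1), tolerance = 1e-12)
  }
})

test_that("increasing desired stimulation increases the command monotonically", {
  s <- seq(0, 1, by = 0.1)
  u <- stimulation_to_command(s, 0.1, 20, 0.5)
  expect_true(all(diff(u) > 0))
  # S_des = 0 puts the reflex exactly at threshold
  expect_equal(stimulation_to_command(0, 0.1, 20, 0.5), 0.5 / 20 - 0.1)
})

stance_gains <- function() {
  g <- default_gait()
  list(g1_vas = g$g1_vas, g1_sol = g$g1_sol, g1_gas = g$g1_gas,
       ko_phi = g$ko_phi, ko_vas = g$ko_vas, ko_bfsh = g$ko_bfsh,
       gp_s = g$gp_s, gd_s = g$gd_s, th_ref_s = g$th_ref_s,
       gp_f = g$gp_f, gd_f = g$gd_f, g4 = g$g4,
       g_ta = g$g_ta, loff_ta = g$loff_ta, gsup_ta = g$gsup_ta,
       Smin = 0.01)
}

rest_signals <- function(gains) {
  list(Fn_vas = 0, Fn_sol = 0, Fn_gas = 0, knee = 0.6, dknee = 0,
       pitch = gains$th_ref_s, dpitch = 0, roll_rel = 0, droll_rel = 0,
       load = 0.5, tau_sw_hip = 0, lce_ta_norm = gains$loff_ta)
}

test_that("stance modules at rest emit only baseline tone", {
  g <- stance_gains()
  S <- stance_stimulations(g, rest_signals(g))
  expect_true(all(S == g$Smin))
})

test_that("trunk lean recruits hip extensors monotonically with load weighting", {
  g <- stance_gains()
  s <- rest_signals(g)
  leans <- g$th_ref_s + seq(0, 0.3, by = 0.05)
  sglu <- vapply(leans, function(p) {
    s$pitch <- p
    stance_stimulations(g, s)["GLU"]
  }, numeric(1))
  expect_true(all(diff(sglu) >= 0))
  expect_gt(sglu[length(sglu)], sglu[1])
  # backward lean recruits the hip flexors instead
  s$pitch <- g$th_ref_s - 0.2
  S <- stance_stimulations(g, s)
  expect_gt(S["HFL"], g$Smin)
  expect_equal(unname(S["GLU"]), g$Smin)
  # no load, no trunk response
  s$load <- 0
  expect_equal(unname(stance_stimulations(g, s)["HFL"]), g$Smin)
})

test_that("positive force feedback on the plantarflexors is monotone", {
  g <- stance_gains()
  s <- rest_signals(g)
  fr <- seq(0, 0.5, by = 0.1)
  ssol <- vapply(fr, function(f) {
    s$Fn_sol <- f
    stance_stimulations(g, s)["SOL"]
  }, numeric(1))
  expect_true(all(diff(ssol) > 0))
})

test_that("knee overextension suppresses VAS and recruits BFSH", {
  g <- stance_gains()
  s <- rest_signals(g)
  s$Fn_vas <- 0.3
  ref <- stance_stimulations(g, s)
  s$knee <- 0.05
  s$dknee <- -2  # extending
  S <- stance_stimulations(g, s)
  expect_lt(S["VAS"], ref["VAS"])
  expect_gt(S["BFSH"], ref["BFSH"])
})

test_that("swing-leg interaction torques are compensated at the stance hip", {
  g <- stance_gains()
  s <- rest_signals(g)
  s$tau_sw_hip <- 80
  S <- stance_stimulations(g, s)
  expect_gt(S["GLU"], g$Smin)
  s$tau_sw_hip <- -80
  S <- stance_stimulations(g, s)
  expect_gt(S["HFL"], g$Smin)
})

test_that("all stance stimulations stay within [Smin, 1]", {
  g <- stance_gains()
  set.seed(6)
  for (rep in 1:200) {
    s <- list(Fn_vas = runif(1), Fn_sol = runif(1), Fn_gas = runif(1),
              knee = runif(1, -0.2, 2), dknee = rnorm(1, 0, 5),
              pitch = rnorm(1, 0.1, 0.3), dpitch = rnorm(1, 0, 2),
              roll_rel = rnorm(1, 0, 0.3), droll_rel = rnorm(1, 0, 2),
              load = runif(1), tau_sw_hip = rnorm(1, 0, 150),
              lce_ta_norm = runif(1, 0.6, 1.4))
    S <- stance_stimulations(g, s)
    expect_true(all(S >= g$Smin - 1e-12 & S <= 1 + 1e-12))
  }
})
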