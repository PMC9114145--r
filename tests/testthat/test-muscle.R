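mus <- default_muscles()

test_that("the muscle roster matches the model layout", {
  expect_equal(nrow(mus), 22)
  for (lg in 0:1) {
    leg <- mus[mus$leg == lg, ]
    expect_equal(nrow(leg), 11)
    pitch <- leg[leg$dof1 %in% c(0, 2, 3), ]
    roll <- leg[leg$dof1 == 1, ]
    expect_equal(nrow(pitch), 9)
    expect_equal(nrow(roll), 2)
  }
  # biarticular muscles span two DoFs
  expect_equal(sum(mus$ndof == 2), 6)  # HAM, RF, GAS on each side
})

test_that("isometric identities of the contractile element", {
  i <- match("VAS_L", mus$name)
  lopt <- mus$lopt[i]
  # zero activation in mid range: no force at all
  f0 <- mtu_force(mus, i, l_ce = lopt, v_ce = 0, A = 0)
  expect_equal(f0$F_ce, 0)
  expect_equal(f0$F_mtu, 0)
  # full activation at the optimum: F_ce = Fmax
  f1 <- mtu_force(mus, i, l_ce = lopt, v_ce = 0, A = 1)
  expect_equal(f1$F_ce, mus$Fmax[i])
  expect_equal(f1$f_l, 1)
  expect_equal(f1$f_v, 1)
})

test_that("passive parallel element engages and rises with stretch", {
  i <- match("GAS_L", mus$name)
  lopt <- mus$lopt[i]
  w <- mus$w[i]
  ls <- seq(lopt * (1 + 0.5 * w) + 1e-4, lopt * (1 + 1.2 * w), length.out = 20)
  fpe <- vapply(ls, function(l) mtu_force(mus, i, l, 0, 0)$F_pe, numeric(1))
  expect_true(all(fpe > 0))
  expect_true(all(diff(fpe) > 0))
  # disengaged below the engagement length
  expect_equal(mtu_force(mus, i, lopt, 0, 0)$F_pe, 0)
  # buffer engages under compression (SOL has a finite compression limit)
  k <- match("SOL_L", mus$name)
  lmin <- mus$lopt[k] * (1 - mus$w[k])
  expect_gt(mtu_force(mus, k, lmin * 0.9, 0, 0)$F_be, 0)
  expect_equal(mtu_force(mus, k, lmin * 1.1, 0, 0)$F_be, 0)
})

test_that("f_l is unimodal with maximum 1 at the optimal length", {
  i <- match("SOL_L", mus$name)
  lopt <- mus$lopt[i]
  ls <- seq(0.4 * lopt, 1.6 * lopt, length.out = 101)
  fl <- muscle_curves(mus, rep(ls[1], 22), rep(0, 22))  # warm call
  fl <- vapply(ls, function(l) mtu_force(mus, i, l, 0, 1)$f_l, numeric(1))
  imax <- which.max(fl)
  expect_equal(ls[imax], lopt, tolerance = 0.02)
  expect_equal(max(fl), 1)
  expect_true(all(diff(fl[seq_len(imax)]) >= -1e-12))
  expect_true(all(diff(fl[imax:length(fl)]) <= 1e-12))
})

test_that("f_v is monotone from shortening to lengthening and bounded", {
  i <- match("HFL_L", mus$name)
  vmax <- mus$vmax[i]
  vs <- seq(-1.2 * vmax, 1.2 * vmax, length.out = 201)
  fv <- vapply(vs, function(v) mtu_force(mus, i, mus$lopt[i], v, 1)$f_v,
               numeric(1))
  expect_true(all(diff(fv) >= -1e-12))
  expect_equal(fv[1], 0)
  expect_true(all(fv <= mus$fvN[i]))
  expect_equal(fv[vs == 0][1], 1, tolerance = 0.05)
})

test_that("activation dynamics: fixed point, step response, decay, bounds", {
  expect_equal(activation_step(0.4, 0.4, 1e-3, 0.01), 0.4)
  # closed-form step response 1 - exp(-t/tau)
  A <- 0
  dt <- 1e-5
  for (k in seq_len(1000)) A <- activation_step(A, 1, dt, 0.01)
  expect_equal(A, 1 - exp(-0.01 / 0.01), tolerance = 1e-3)
  # monotone decay from 1 under zero stimulation
  A <- 1
  tr <- numeric(50)
  for (k in 1:50) {
    A <- activation_step(A, 0, 1e-3, 0.01)
    tr[k] <- A
  }
  expect_true(all(diff(tr) < 0))
  expect_true(all(tr >= 0 & tr <= 1))
  # stays in [0, 1] for arbitrary bounded stimulation histories
  set.seed(3)
  A <- 0.5
  for (k in 1:500) A <- activation_step(A, runif(1), 1e-3, 0.01)
  expect_true(A >= 0 && A <= 1)
})

test_that("moment arms are sparse according to anatomy", {
  th <- airborne_theta()
  g <- muscle_geometry(mus, th)
  # monoarticular hip flexor has no arm at knee or ankle
  expect_equal(unname(g$C[9, "HFL_L"]), 0)
  expect_equal(unname(g$C[10, "HFL_L"]), 0)
  # gastrocnemius is biarticular: knee AND ankle
  expect_true(g$C[9, "GAS_L"] != 0)
  expect_true(g$C[10, "GAS_L"] != 0)
  # trunk rows carry no muscle
  expect_true(all(g$C[1:6, ] == 0))
  # left-leg muscles do not span right-leg joints
  expect_true(all(g$C[11:14, mus$leg == 0] == 0))
})

test_that("moment arms equal the negative length gradient (virtual work)", {
  set.seed(4)
  h <- 1e-7
  for (rep in 1:30) {
    q <- airborne_theta(runif(4, -0.3, 1.2), runif(4, -0.3, 1.2))
    g <- muscle_geometry(mus, q)
    j <- sample(7:14, 1)
    qp <- q
    qp[j] <- qp[j] + h
    gp <- muscle_geometry(mus, qp)
    dldq <- (gp$l_mtu - g$l_mtu) / h
    expect_lt(max(abs(dldq + g$C[j, ])), 1e-4)
  }
})

test_that("torques from forces: linearity, sparsity and antagonist cancellation", {
  th <- airborne_theta()
  g <- muscle_geometry(mus, th)
  expect_equal(torques_from_forces(g$C, rep(0, 22)), rep(0, 14))
  F <- rep(0, 22)
  F[match("VAS_L", mus$name)] <- 100
  tau <- torques_from_forces(g$C, F)
  expect_true(all(tau[-9] == 0))  # only the left knee
  expect_error(torques_from_forces(g$C, rep(-1, 22)))
  # equal and opposite arms cancel under equal force
  C2 <- matrix(0, 1, 2)
  C2[1, ] <- c(0.05, -0.05)
  expect_equal(torques_from_forces(C2, c(10, 10)), 0)
})

test_that("CE-SE equilibrium: slack tendon shortens CE, taut tendon balances", {
  i <- match("SOL_L", mus$name)
  lopt <- mus$lopt[i]
  lsl <- mus$lslack[i]
  # slack: lmtu shorter than lce + lslack -> CE shortens
  eq <- cpp_mtu_equilibrium(flexgait:::mtbl_list(mus), i, lopt,
                            0.5, lopt + lsl - 0.01)
  expect_lt(eq$v_ce, 0)
  expect_equal(eq$F_se, 0)
  # stretched tendon with activation: positive force, finite velocity
  eq2 <- cpp_mtu_equilibrium(flexgait:::mtbl_list(mus), i, lopt,
                             0.5, lopt + lsl * (1 + 0.03))
  expect_gt(eq2$F_se, 0)
  expect_true(abs(eq2$v_ce) <= 1.5 * mus$vmax[i])
})
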