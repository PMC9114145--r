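test_that("CMA-ES reaches 1e-8 on a 10-D sphere within 5000 evaluations", {
  r <- cmaes(function(x) sum(x^2), rep(3, 10), sigma0 = 1, budget = 5000,
             seed = 1, target = 1e-9)
  expect_lt(r$value, 1e-8)
  expect_lte(r$evals, 5000)
})

test_that("CMA-ES is deterministic under a fixed seed", {
  f <- function(x) sum((x - 1)^2) + 0.5 * sum(abs(x))
  r1 <- cmaes(f, rep(0, 5), sigma0 = 0.5, budget = 300, seed = 7)
  r2 <- cmaes(f, rep(0, 5), sigma0 = 0.5, budget = 300, seed = 7)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$history, r2$history)
})

test_that("CMA-ES respects box bounds", {
  r <- cmaes(function(x) sum((x - 2)^2), rep(0.5, 4), sigma0 = 0.3,
             lower = 0, upper = 1, budget = 600, seed = 3)
  expect_true(all(r$par >= 0 & r$par <= 1))
  expect_equal(r$par, rep(1, 4), tolerance = 1e-2)
})

test_that("walking cost orders falling strictly below non-falling candidates", {
  # the two-stage cost: J = 2 c0 - x_fall when falling, c0 + d_steady
  # otherwise, with d_steady capped at c0
  m <- fg_test_model()
  r <- evaluate_cost(m, duration = 3)
  if (r$fell) {
    expect_equal(r$J, 2000 - max(r$x_fall, 0))
    expect_gte(r$J, 1000)
  } else {
    expect_gte(r$J, 1000)
    expect_lte(r$J, 2000)
  }
  # a run too short for any stride counts as maximally unsteady, which
  # keeps the falling / non-falling ordering strict
  r2 <- evaluate_cost(m, duration = 0.6)
  expect_lte(r2$J, 2000)
})

test_that("parameter vector mapping is bijective and 55-dimensional", {
  m <- fg_test_model()
  v <- params_to_vector(m)
  expect_length(v, 55)
  expect_false(any(duplicated(names(v))))
  m2 <- vector_to_params(m, v)
  expect_equal(params_to_vector(m2), v)
  # a perturbed vector round-trips too
  v2 <- v * 1.03 + 0.001
  expect_equal(unname(params_to_vector(vector_to_params(m, v2))),
               unname(v2), tolerance = 1e-12)
  b <- param_bounds()
  expect_equal(rownames(b), names(v))
  expect_true(all(b[, "lower"] < b[, "upper"]))
})
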