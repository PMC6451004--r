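test_that("analytic limits of the depletion solution hold", {
  # h = 0: pure exponential depletion
  expect_equal(fr_predict_typeII(100, time = 1, a = 1, h = 0),
               100 * (1 - exp(-1)), tolerance = 1e-12)
  a_grid <- c(0.1, 1, 2.686)
  for (a in a_grid) {
    expect_equal(fr_predict_typeII(design_densities, time = 4, a = a, h = 0),
                 design_densities * (1 - exp(-4 * a)), tolerance = 1e-12)
  }
  # zero exposure or zero prey eats nothing
  expect_identical(fr_predict_typeII(100, time = 0, a = 2, h = 0.01), 0)
  expect_identical(fr_predict_flexible(0, time = 4, b = 1, q = 0.5, h = 0.01), 0)
  # long exposure without handling consumes everything
  expect_equal(fr_predict_typeII(50, time = 1e4, a = 1, h = 0), 50,
               tolerance = 1e-9)
})

test_that("q = 0 flexible model collapses exactly onto type II", {
  for (x in c(0.1, 1, 2.686)) {
    expect_equal(
      fr_predict_flexible(design_densities, time = 4, b = x, q = 0, h = 0.003),
      fr_predict_typeII(design_densities, time = 4, a = x, h = 0.003),
      tolerance = 1e-12)
  }
})

test_that("closed form matches frozen bisection-oracle values", {
  # values computed beforehand with 200-step bisection on the residual
  expect_equal(fr_predict_typeII(300, time = 4, a = 2.686, h = 0.001),
               299.9855123170, tolerance = 1e-8)
  expect_equal(fr_predict_flexible(150, time = 4, b = 0.781, q = 0.426,
                                   h = 0.003),
               149.9999999901, tolerance = 1e-8)
})

test_that("predictions zero the implicit residual; residual signs bracket it", {
  cases <- expand.grid(a = c(0.1, 1, 2.686), h = c(0.001, 0.006),
                       n0 = c(5, 50, 300), t = c(1 / 6, 4))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    ne <- fr_predict_typeII(cs$n0, cs$t, a = cs$a, h = cs$h)
    expect_lt(abs(fr_implicit_residual(ne, cs$n0, cs$t, cs$a, cs$h)), 1e-9)
    expect_lt(fr_implicit_residual(0, cs$n0, cs$t, cs$a, cs$h), 0)
    expect_gt(fr_implicit_residual(cs$n0, cs$n0, cs$t, cs$a, cs$h), 0)
    expect_true(ne >= 0 && ne < cs$n0)
    expect_lt(ne * cs$h, cs$t)   # handling cannot exceed the exposure
  }
})

test_that("ODE integration of the disc equation agrees with the closed form", {
  expect_equal(fr_ode_eaten(100, 1, a_eff = 1, h = 0), 100 * (1 - exp(-1)),
               tolerance = 1e-8)
  expect_identical(fr_ode_eaten(100, 0, a_eff = 1, h = 0.01), 0)
  for (a in c(0.1, 2.686)) {
    for (h in c(0, 0.006)) {
      n0 <- c(5, 30, 300)
      expect_equal(fr_ode_eaten(n0, 4, a_eff = a, h = h),
                   fr_predict_typeII(n0, 4, a = a, h = h), tolerance = 1e-6)
    }
  }
})

test_that("consumption is monotone in time, attack rate, density and handling", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 0.05, 5)
    h <- runif(1, 0, 0.01)
    n0 <- sample(5:300, 1)
    t <- runif(1, 0.05, 4)
    ne <- fr_predict_typeII(n0, t, a = a, h = h)
    expect_gt(fr_predict_typeII(n0, t * 1.5, a = a, h = h), ne)
    expect_gt(fr_predict_typeII(n0, t, a = a * 1.5, h = h), ne)
    expect_gt(fr_predict_typeII(n0 + 50, t, a = a, h = h), ne)
    expect_lt(fr_predict_typeII(n0, t, a = a, h = h + 0.005), ne)
  }
})

test_that("extreme exponents trigger the bisection fallback, not overflow", {
  # h * N0 >> T makes the Lambert argument overflow; result must still solve
  # the implicit equation
  ne <- fr_predict_typeII(300, time = 0.1, a = 500, h = 0.05)
  expect_true(is.finite(ne))
  expect_lt(abs(fr_implicit_residual(ne, 300, 0.1, 500, 0.05)), 1e-6)
  expect_lt(ne, 0.1 / 0.05 + 1)   # handling-limited ceiling
})

test_that("invalid model inputs are rejected", {
  expect_error(fr_predict_typeII(-5, 4, a = 1, h = 0.01), "non-negative")
  expect_error(fr_predict_typeII(5, -1, a = 1, h = 0.01), "non-negative")
  expect_error(fr_predict_typeII(5, 4, a = -1, h = 0.01), "positive")
  expect_error(fr_predict_flexible(5, 4, b = 1, q = -1.2, h = 0), "> -1")
})
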