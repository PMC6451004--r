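prepared_row <- function(n0, ne, tt = 1) {
  tibble::tibble(prey_size = "small", substrate = "absent",
                 nominal_density = n0, replicate = seq_along(n0),
                 corrected_initial = as.integer(n0), eaten = as.integer(ne),
                 exposure_time = tt)
}

test_that("the binomial likelihood matches hand and oracle computations", {
  # a = log 2, h = 0, T = 1 predicts p = 1/2; one success of two trials
  one <- prepared_row(2, 1)
  expect_equal(fr_nll(c(a = log(2), h = 0), one, "typeII"), log(2),
               tolerance = 1e-9)
  # nothing eaten under a vanishing attack rate contributes ~0
  none <- prepared_row(c(50, 100), c(0, 0))
  expect_lt(fr_nll(c(a = 1e-8, h = 0), none, "typeII"), 1e-4)
  # full datasets match a longhand factorial-formula summation
  prep <- sim_prepared(truth_flexible(), seed = 3)
  for (pars in list(c(b = 0.173, q = 0.739, h = 0.003),
                    c(b = 0.5, q = 0.2, h = 0.001),
                    c(b = 2, q = -0.3, h = 0.01))) {
    expect_equal(
      fr_nll(pars, prep, "flexible"),
      oracle_nll(prep, function(n0, tt) {
        fr_predict_flexible(n0, tt, b = pars[["b"]], q = pars[["q"]],
                            h = pars[["h"]])
      }),
      tolerance = 1e-8)
  }
  prep2 <- sim_prepared(truth_typeII(), seed = 4)
  expect_equal(
    fr_nll(c(a = 2.686, h = 0.001), prep2, "typeII"),
    oracle_nll(prep2, function(n0, tt) {
      fr_predict_typeII(n0, tt, a = 2.686, h = 0.001)
    }),
    tolerance = 1e-8)
})

test_that("out-of-domain parameters penalize with +Inf instead of erroring", {
  prep <- prepared_row(c(10, 20, 30), c(5, 8, 10))
  expect_identical(fr_nll(c(a = -1, h = 0.01), prep, "typeII"), Inf)
  expect_identical(fr_nll(c(a = 1, h = -0.01), prep, "typeII"), Inf)
  expect_identical(fr_nll(c(b = 1, q = -1.5, h = 0.01), prep, "flexible"), Inf)
  expect_error(fr_nll(c(a = 1, h = 0), prep[0, ], "typeII"), "non-empty")
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(fr_aicc(-100, 2, 66), 204.19048, tolerance = 1e-6)
  expect_equal(fr_aicc(-100, 3, 66), 206.38710, tolerance = 1e-6)
  expect_equal(fr_aicc(-100, 2, 1e9), 204, tolerance = 1e-6)
  expect_error(fr_aicc(-100, 3, 4), "n_trials")
})

test_that("Wald tests reproduce hand-checked p-values", {
  expect_equal(round(fr_wald(0.362, 0.166)$p.value, 3), 0.029)
  expect_equal(round(fr_wald(0.173, 0.059)$p.value, 3), 0.003)
  expect_equal(fr_wald(0, 0.5)$p.value, 1)
  expect_equal(fr_wald(1.2, 0.3, null = 1.2)$p.value, 1)
  expect_error(fr_wald(1, 0), "positive")
  expect_error(fr_wald(1, -0.1), "positive")
})

test_that("noise-free data at the design densities recover the parameters", {
  # deterministic dataset: eaten = rounded expectation, 6 replicates
  n0 <- rep(design_densities, each = 6)
  tt <- 1 / 6
  ne <- round(fr_predict_typeII(n0, tt, a = 2.686, h = 0.001))
  prep <- prepared_row(n0, ne, tt)
  fit <- fr_fit(prep, "typeII", seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["a"]] - 2.686) / 2.686, 0.10)
  expect_lt(abs(fit$estimates[["h"]] - 0.001) / 0.001, 0.25)
  expect_true(all(diag(fit$vcov) >= 0))
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-10)
})

test_that("the flexible model nests type II", {
  prep <- sim_prepared(truth_flexible(), seed = 5)
  # identical likelihood surface at q = 0
  for (pars in list(c(0.5, 0.002), c(2, 0.004))) {
    expect_equal(
      fr_nll(c(b = pars[1], q = 0, h = pars[2]), prep, "flexible"),
      fr_nll(c(a = pars[1], h = pars[2]), prep, "typeII"),
      tolerance = 1e-9)
  }
  # the 3-parameter optimum can only improve on the 2-parameter optimum
  f2 <- fr_fit(prep, "typeII", seed = 1)
  ff <- fr_fit(prep, "flexible", seed = 1)
  expect_gte(ff$logLik, f2$logLik - 1e-4)
})

test_that("fitting is deterministic given a seed", {
  prep <- sim_prepared(truth_flexible(), seed = 6)
  f1 <- fr_fit(prep, "flexible", seed = 99)
  f2 <- fr_fit(prep, "flexible", seed = 99)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$logLik, f2$logLik)
})

test_that("degenerate and undersized data are refused gracefully", {
  prep <- prepared_row(c(10, 20, 30, 50), c(0, 0, 0, 0))
  fit <- fr_fit(prep, "typeII")
  expect_false(fit$converged)
  expect_match(fit$message, "Degenerate")
  expect_error(fr_fit(prepared_row(c(10, 10), c(1, 2)), "typeII"),
               "distinct densities")
})

test_that("fit results expose tidy, glance and prediction interfaces", {
  prep <- sim_prepared(truth_flexible(), seed = 8)
  fit <- fr_fit(prep, "flexible", seed = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_identical(td$term, c("b", "q", "h"))
  gl <- glance(fit)
  expect_identical(gl$df, 3L)
  expect_equal(gl$AICc, fr_aicc(gl$logLik, 3, gl$nobs))
  expect_equal(predict(fit, 0), 0)
  expect_length(predict(fit, c(5, 50, 300)), 3)
})

test_that("AICc model comparison prefers parsimony on ties and failures", {
  stub <- function(model, aicc, converged = TRUE) {
    k <- if (model == "typeII") 2 else 3
    funcresp:::new_fr_fit(
      model, estimates = setNames(rep(1, k), if (k == 2) c("a", "h")
                                  else c("b", "q", "h")),
      se = setNames(rep(1, k), letters[1:k]), vcov = diag(k),
      logLik = -10, aicc = aicc, n_trials = 66, converged = converged,
      n_restarts_used = 1L, prepared = NULL)
  }
  # magnitudes as printed for the small-prey/no-substrate treatment
  cmp <- fr_compare_models(stub("typeII", 773.957), stub("flexible", 692.081))
  expect_identical(cmp$preferred, "flexible")
  expect_equal(cmp$delta_aicc, 81.876, tolerance = 1e-6)
  expect_identical(
    fr_compare_models(stub("typeII", 100), stub("flexible", 100))$preferred,
    "typeII")
  expect_warning(
    cmp2 <- fr_compare_models(stub("typeII", 100),
                              stub("flexible", 90, converged = FALSE)),
    "did not converge")
  expect_identical(cmp2$preferred, "typeII")
  expect_error(fr_compare_models(stub("flexible", 1), stub("flexible", 2)),
               "type II fit first")
})
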