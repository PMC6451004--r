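#' Binomial negative log-likelihood of a functional-response model
#'
#' Each prepared trial contributes `-log Binomial(eaten | corrected_initial,
#' p)` where `p` is the model-predicted proportion eaten,
#' `predict(N0, T) / N0`, clipped to `[1e-9, 1 - 1e-9]`. Rows with a zero
#' corrected initial contribute nothing. Parameter values outside their
#' domain return `+Inf` (a penalty, not an error) so optimizers stay
#' in-domain.
#'
#' @param params Named numeric vector: `c(a, h)` for `"typeII"`,
#'   `c(b, q, h)` for `"flexible"`.
#' @param prepared A prepared-trials tibble from [fr_prepare_trials()].
#' @param model `"typeII"` or `"flexible"`.
#' @return The negative log-likelihood (scalar).
#' @export
fr_nll <- function(params, prepared, model = c("typeII", "flexible")) {
  model <- match.arg(model)
  if (nrow(prepared) == 0) abort("`prepared` must be non-empty.")
  nll <- make_nll(prepared, model)
  if (model == "typeII") {
    a <- params[["a"]]; h <- params[["h"]]
    if (!is.finite(a) || !is.finite(h) || a <= 0 || h < 0) return(Inf)
    nll(c(log(a), log(max(h, 1e-300))))
  } else {
    b <- params[["b"]]; q <- params[["q"]]; h <- params[["h"]]
    if (!is.finite(b) || !is.finite(q) || !is.finite(h) ||
        b <= 0 || h < 0 || q <= -1) return(Inf)
    nll(c(log(b), q, log(max(h, 1e-300))))
  }
}

# closure over the data arrays; parameters on the fitting scale
# (log for positive rates, raw for q)
make_nll <- function(prepared, model) {
  keep <- prepared$corrected_initial > 0
  make_nll_vec(as.numeric(prepared$corrected_initial[keep]),
               as.numeric(prepared$eaten[keep]),
               as.numeric(prepared$exposure_time[keep]), model)
}

make_nll_vec <- function(n0, ne, tt, model) {
  if (model == "typeII") {
    function(pt) {
      if (any(!is.finite(pt))) return(Inf)
      pred <- rogers_fast(exp(pt[1]), exp(pt[2]), n0, tt)
      binom_nll(ne, n0, pred)
    }
  } else {
    lg_n0 <- log(n0)
    function(pt) {
      if (any(!is.finite(pt)) || pt[2] <= -1) return(Inf)
      a_eff <- exp(pt[1] + pt[2] * lg_n0)
      pred <- rogers_fast(a_eff, exp(pt[3]), n0, tt)
      binom_nll(ne, n0, pred)
    }
  }
}

binom_nll <- function(ne, n0, pred) {
  p <- pmin(pmax(pred / n0, 1e-9), 1 - 1e-9)
  val <- -sum(dbinom(ne, n0, p, log = TRUE))
  if (!is.finite(val)) Inf else val
}

# unchecked vectorized Rogers solution for the optimizer hot path
rogers_fast <- function(a_eff, h, n0, tt) {
  if (h <= 0) return(n0 * (1 - exp(-a_eff * tt)))
  z <- a_eff * h * n0 * exp(-a_eff * (tt - h * n0))
  if (all(is.finite(z))) {
    ne <- n0 - lamw0_fast(z) / (a_eff * h)
  } else {
    ne <- numeric(length(n0))
    fin <- is.finite(z)
    a_eff <- rep_len(a_eff, length(n0))
    tt <- rep_len(tt, length(n0))
    ne[fin] <- n0[fin] - lamw0_fast(z[fin]) / (a_eff[fin] * h)
    for (i in which(!fin)) ne[i] <- bisect_eaten(a_eff[i], h, n0[i], tt[i])
  }
  pmin(pmax(ne, 0), n0)
}

#' Fit a prey-depletion functional response by maximum likelihood
#'
#' Maximizes the binomial likelihood of [fr_nll()] with a derivative-free
#' Nelder-Mead simplex, restarted from jittered copies of a Holling-disc
#' moment heuristic (low-density consumption slope for the attack/capture
#' rate, reciprocal high-density asymptote for the handling time, `q = 0.5`
#' midway in the plausible sigmoidality range). Positive parameters are
#' optimized on the log scale; `q` on the raw scale. Standard errors come
#' from the inverse of a numerically differentiated Hessian at the optimum,
#' mapped to the natural scale by the delta method.
#'
#' @inheritParams fr_nll
#' @param init Optional named vector of natural-scale start values.
#' @param n_restarts Number of optimizer restarts (first unjittered).
#' @param seed Optional integer seed for the restart jitter.
#' @return An object of class `fr_fit`: estimates, standard errors,
#'   natural-scale covariance, log-likelihood, AICc, convergence flag.
#'   Degenerate data (no prey eaten anywhere) yields `converged = FALSE`
#'   with an explanatory message rather than an error.
#' @examples
#' prepared <- fr_prepare_trials(fr_simulate_trials(seed = 1))
#' fit <- fr_fit(dplyr::filter(prepared, prey_size == "small",
#'                             substrate == "absent"), model = "flexible")
#' tidy(fit)
#' glance(fit)
#' @export
fr_fit <- function(prepared, model = c("typeII", "flexible"), init = NULL,
                   n_restarts = 5, seed = NULL) {
  model <- match.arg(model)
  k <- if (model == "typeII") 2L else 3L
  par_names <- if (model == "typeII") c("a", "h") else c("b", "q", "h")
  n <- nrow(prepared)
  if (n < k + 1 || dplyr::n_distinct(prepared$corrected_initial) < 3) {
    abort("Need more trials than parameters, spanning >= 3 distinct densities.")
  }
  if (!is.null(seed)) set.seed(seed)
  if (all(prepared$eaten == 0)) {
    return(new_fr_fit(
      model, estimates = setNames(rep(NA_real_, k), par_names),
      se = setNames(rep(NA_real_, k), par_names),
      vcov = matrix(NA_real_, k, k), logLik = NA_real_,
      aicc = NA_real_, n_trials = n, converged = FALSE,
      n_restarts_used = 0L, prepared = prepared,
      message = "Degenerate data: no prey eaten in any trial."))
  }
  nll <- make_nll(prepared, model)
  start <- fr_start_values(prepared, model)
  if (!is.null(init)) {
    start <- natural_to_fitting(init[par_names], model)
  }
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    st <- start
    if (r > 1) {
      st <- st + rnorm(k, 0, ifelse(par_names == "q", 0.4, 0.7))
    }
    opt <- tryCatch(
      optim(st, nll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(new_fr_fit(
      model, estimates = setNames(rep(NA_real_, k), par_names),
      se = setNames(rep(NA_real_, k), par_names),
      vcov = matrix(NA_real_, k, k), logLik = NA_real_, aicc = NA_real_,
      n_trials = n, converged = FALSE, n_restarts_used = n_restarts,
      prepared = prepared, message = "All optimizer restarts failed."))
  }
  est <- fitting_to_natural(best$par, model, par_names)
  hess_ok <- TRUE
  vc <- matrix(NA_real_, k, k, dimnames = list(par_names, par_names))
  se <- setNames(rep(NA_real_, k), par_names)
  H <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
  cov_t <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(cov_t) || any(!is.finite(cov_t)) || any(diag(cov_t) <= 0)) {
    hess_ok <- FALSE
  } else {
    jac <- diag(ifelse(par_names == "q", 1, est), nrow = k)
    vc <- jac %*% cov_t %*% jac
    dimnames(vc) <- list(par_names, par_names)
    se <- setNames(sqrt(diag(vc)), par_names)
  }
  ll <- -best$value
  new_fr_fit(
    model, estimates = est, se = se, vcov = vc, logLik = ll,
    aicc = fr_aicc(ll, k, n), n_trials = n,
    converged = best$convergence == 0 && hess_ok,
    n_restarts_used = max(1L, n_restarts), prepared = prepared,
    message = if (hess_ok) NULL else "Hessian not invertible at the optimum.")
}

new_fr_fit <- function(model, estimates, se, vcov, logLik, aicc, n_trials,
                       converged, n_restarts_used, prepared, message = NULL) {
  structure(
    list(model = model, estimates = estimates, se = se, vcov = vcov,
         logLik = logLik, aicc = aicc, n_trials = n_trials,
         n_params = length(estimates), converged = converged,
         n_restarts_used = n_restarts_used, data = prepared,
         message = message),
    class = "fr_fit")
}

natural_to_fitting <- function(est, model) {
  if (model == "typeII") c(log(est[["a"]]), log(est[["h"]])) else
    c(log(est[["b"]]), est[["q"]], log(est[["h"]]))
}

fitting_to_natural <- function(pt, model, par_names) {
  out <- if (model == "typeII") c(exp(pt[1]), exp(pt[2])) else
    c(exp(pt[1]), pt[2], exp(pt[3]))
  setNames(out, par_names)
}

# moment heuristic: exponential-depletion inversion at the lowest densities
# for the attack rate, reciprocal asymptote for the handling time
fr_start_values <- function(prepared, model) {
  keep <- prepared$corrected_initial > 0
  dd <- tibble::tibble(n0 = prepared$corrected_initial[keep],
                       ne = prepared$eaten[keep],
                       tt = prepared$exposure_time[keep])
  by_dens <- dd |>
    dplyr::group_by(.data$n0) |>
    dplyr::summarise(mean_ne = mean(.data$ne), tt = mean(.data$tt),
                     .groups = "drop") |>
    dplyr::arrange(.data$n0)
  low <- head(by_dens, 3)
  p_low <- min(sum(low$mean_ne) / sum(low$n0), 0.95)
  t_bar <- mean(dd$tt)
  a0 <- max(-log(1 - max(p_low, 1e-3)) / t_bar, 1e-3)
  h0 <- min(max(t_bar / max(max(by_dens$mean_ne), 1), 1e-4), t_bar)
  if (model == "typeII") {
    c(log(a0), log(h0))
  } else {
    q0 <- 0.5
    d_low <- exp(mean(log(low$n0)))
    b0 <- max(a0 / d_low^q0, 1e-4)
    c(log(b0), q0, log(h0))
  }
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 LL + 2k + 2k(k + 1)/(n - k - 1)`; lower values indicate a
#' better parsimony-adjusted fit.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param n_params Number of free parameters `k`.
#' @param n_trials Number of observations `n` (must exceed `k + 1`).
#' @return The AICc value.
#' @examples
#' fr_aicc(-100, 2, 66)
#' @export
fr_aicc <- function(log_likelihood, n_params, n_trials) {
  if (n_trials <= n_params + 1) {
    abort("AICc requires n_trials > n_params + 1.")
  }
  -2 * log_likelihood + 2 * n_params +
    2 * n_params * (n_params + 1) / (n_trials - n_params - 1)
}

#' Two-sided Wald test
#'
#' `z = (estimate - null) / SE`, `p = 2 (1 - Phi(|z|))`.
#'
#' @param estimate Parameter estimate.
#' @param se Standard error (positive).
#' @param null Null value (default 0).
#' @return A tibble with `estimate`, `se`, `null`, `statistic`, `p.value`.
#' @examples
#' fr_wald(0.362, 0.166)   # p ~ 0.029
#' @export
fr_wald <- function(estimate, se, null = 0) {
  if (any(!is.finite(se)) || any(se <= 0)) abort("`se` must be positive.")
  z <- (estimate - null) / se
  tibble::tibble(estimate = estimate, se = se, null = null,
                 statistic = z, p.value = 2 * pnorm(-abs(z)))
}

#' Classify a flexible fit as sigmoidal (type III)
#'
#' A flexible fit is labelled type III only when the scaling exponent is
#' positive and its two-sided Wald test against zero is significant.
#'
#' @param fit A converged flexible `fr_fit`.
#' @param alpha Significance level (default 0.05).
#' @return `TRUE` if `q > 0` and `p < alpha`, otherwise `FALSE`.
#' @export
fr_is_typeIII <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "fr_fit"))
  if (fit$model != "flexible" || !fit$converged) return(FALSE)
  q <- fit$estimates[["q"]]
  p <- fr_wald(q, fit$se[["q"]])$p.value
  isTRUE(q > 0 && p < alpha)
}

#' Compare type II and flexible fits by AICc
#'
#' The preferred model has the lower AICc; ties and a non-converged flexible
#' fit resolve toward the simpler type II model.
#'
#' @param fit_typeII,fit_flexible `fr_fit` objects on the same prepared data.
#' @return A one-row tibble: `aicc_typeII`, `aicc_flexible`, `delta_aicc`
#'   (type II minus flexible), `preferred`.
#' @export
fr_compare_models <- function(fit_typeII, fit_flexible) {
  stopifnot(inherits(fit_typeII, "fr_fit"), inherits(fit_flexible, "fr_fit"))
  if (fit_typeII$model != "typeII" || fit_flexible$model != "flexible") {
    abort("Pass the type II fit first and the flexible fit second.")
  }
  if (fit_typeII$n_trials != fit_flexible$n_trials) {
    abort("Fits were made on different numbers of trials.")
  }
  if (!fit_flexible$converged) {
    warn("Flexible fit did not converge; preferring type II.")
    preferred <- "typeII"
  } else if (!fit_typeII$converged) {
    warn("Type II fit did not converge; preferring flexible.")
    preferred <- "flexible"
  } else if (fit_flexible$aicc < fit_typeII$aicc) {
    preferred <- "flexible"
  } else {
    preferred <- "typeII"
  }
  tibble::tibble(
    aicc_typeII = fit_typeII$aicc, aicc_flexible = fit_flexible$aicc,
    delta_aicc = fit_typeII$aicc - fit_flexible$aicc, preferred = preferred)
}

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf("<fr_fit> %s prey-depletion functional response\n", x$model))
  if (!is.null(x$message)) cat(" note:", x$message, "\n")
  if (all(is.finite(x$estimates))) {
    for (nm in names(x$estimates)) {
      cat(sprintf("  %-2s %10.5f  (SE %g)\n", nm, x$estimates[[nm]], x$se[[nm]]))
    }
    cat(sprintf("  logLik %.3f  AICc %.3f  n %d  converged %s\n",
                x$logLik, x$aicc, x$n_trials, x$converged))
  }
  invisible(x)
}

#' Tidy a functional-response fit
#'
#' @param x An `fr_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value` (two-sided Wald against zero).
#' @export
tidy.fr_fit <- function(x, ...) {
  z <- x$estimates / x$se
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))))
}

#' One-row model summary of a functional-response fit
#'
#' @param x An `fr_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `logLik`, `AICc`, `nobs`, `df`,
#'   `converged`, `n_restarts_used`.
#' @export
glance.fr_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, logLik = x$logLik, AICc = x$aicc,
    nobs = x$n_trials, df = x$n_params, converged = x$converged,
    n_restarts_used = x$n_restarts_used)
}

#' Predict expected prey eaten from a fitted response
#'
#' @param object An `fr_fit` object.
#' @param initial Initial prey densities to predict at.
#' @param time Exposure time (default: the mean of the fitted data).
#' @param ... Unused.
#' @return Numeric vector of expected prey eaten.
#' @export
predict.fr_fit <- function(object, initial, time = NULL, ...) {
  if (!object$converged && anyNA(object$estimates)) {
    abort("Cannot predict from a degenerate fit.")
  }
  time <- time %||% mean(object$data$exposure_time)
  e <- object$estimates
  if (object$model == "typeII") {
    fr_predict_typeII(initial, time, a = e[["a"]], h = e[["h"]])
  } else {
    fr_predict_flexible(initial, time, b = e[["b"]], q = e[["q"]], h = e[["h"]])
  }
}
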