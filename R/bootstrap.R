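#' Nonparametric bootstrap of a functional-response fit
#'
#' Resamples trials (rows) with replacement to the original sample size,
#' refits the model to each resample starting from the original optimum,
#' and summarizes the converged replicate estimates with 2.5/97.5 percentile
#' confidence intervals. Non-converged replicates are dropped and counted,
#' keeping `n_boot` an upper bound on the replicates used.
#'
#' @param fit A converged `fr_fit`.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional integer seed; the same seed reproduces the
#'   replicate estimates exactly.
#' @param stratify If `TRUE`, resample within density levels, preserving
#'   the balanced design; the default resamples rows freely.
#' @return An object of class `fr_boot`: `replicates` (tibble of converged
#'   replicate estimates), `ci` (tibble `term`, `lower`, `upper`),
#'   `n_requested`, `n_converged`, `seed`, and the original `fit`.
#' @examples
#' prepared <- fr_prepare_trials(fr_simulate_trials(seed = 1))
#' small <- dplyr::filter(prepared, prey_size == "small", substrate == "absent")
#' fit <- fr_fit(small, model = "typeII", seed = 1)
#' boot <- fr_bootstrap(fit, n_boot = 200, seed = 1)
#' tidy(boot)
#' @export
fr_bootstrap <- function(fit, n_boot = 2000, seed = NULL, stratify = FALSE) {
  stopifnot(inherits(fit, "fr_fit"))
  if (!fit$converged) abort("Bootstrap requires a converged original fit.")
  if (!is.null(seed)) set.seed(seed)
  prepared <- fit$data
  n <- nrow(prepared)
  start <- natural_to_fitting(fit$estimates, fit$model)
  par_names <- names(fit$estimates)
  strata <- if (stratify) {
    split(seq_len(n), interaction(prepared$prey_size, prepared$substrate,
                                  prepared$nominal_density, drop = TRUE))
  }
  keep <- prepared$corrected_initial > 0
  n0 <- as.numeric(prepared$corrected_initial)
  ne <- as.numeric(prepared$eaten)
  tt <- as.numeric(prepared$exposure_time)
  est <- matrix(NA_real_, n_boot, length(par_names))
  for (b in seq_len(n_boot)) {
    idx <- if (stratify) {
      unlist(lapply(strata, function(s) s[sample.int(length(s), length(s),
                                                     replace = TRUE)]),
             use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
    idx <- idx[keep[idx]]
    res <- refit_point_vec(n0[idx], ne[idx], tt[idx], fit$model, start)
    if (!is.null(res)) est[b, ] <- res
  }
  ok <- stats::complete.cases(est)
  n_conv <- sum(ok)
  if (n_conv < n_boot / 2) {
    abort(sprintf(
      "Only %d/%d bootstrap replicates converged; the model may not suit these data.",
      n_conv, n_boot))
  }
  reps <- tibble::as_tibble(setNames(as.data.frame(est[ok, , drop = FALSE]),
                                     par_names))
  ci <- purrr::map_dfr(par_names, function(nm) {
    qs <- quantile(reps[[nm]], c(0.025, 0.975), names = FALSE)
    tibble::tibble(term = nm, lower = qs[1], upper = qs[2])
  })
  structure(list(replicates = reps, ci = ci, n_requested = n_boot,
                 n_converged = n_conv, seed = seed, fit = fit),
            class = "fr_boot")
}

# point refit for bootstrap replicates: single start at the original optimum,
# no Hessian (only the estimates are needed)
refit_point_vec <- function(n0, ne, tt, model, start) {
  if (all(ne == 0)) return(NULL)
  nll <- make_nll_vec(n0, ne, tt, model)
  opt <- tryCatch(
    optim(start, nll, method = "Nelder-Mead",
          control = list(maxit = 1000, reltol = 1e-7)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$convergence != 0) return(NULL)
  unname(fitting_to_natural(opt$par, model,
                            if (model == "typeII") c("a", "h") else c("b", "q", "h")))
}

#' @export
print.fr_boot <- function(x, ...) {
  cat(sprintf("<fr_boot> %d/%d converged replicates (%s model)\n",
              x$n_converged, x$n_requested, x$fit$model))
  print(tidy(x))
  invisible(x)
}

#' Tidy a bootstrap result
#'
#' @param x An `fr_boot` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (original MLE), `lower`, `upper`
#'   (2.5/97.5 bootstrap percentiles).
#' @export
tidy.fr_boot <- function(x, ...) {
  dplyr::mutate(x$ci, estimate = unname(x$fit$estimates[.data$term]),
                .after = "term")
}

#' Pointwise bootstrap band of the fitted response curve
#'
#' Evaluates the fitted consumption curve under every converged bootstrap
#' replicate's parameters and returns pointwise 2.5/50/97.5 percentiles over
#' a density grid — the standard way to draw 95% confidence bands around a
#' functional-response curve.
#'
#' @param boot An `fr_boot` object.
#' @param densities Numeric vector of initial prey densities (non-empty).
#' @param time Exposure time (default: mean of the fitted data).
#' @return A tibble of class `fr_band`: `density`, `lower`, `median`,
#'   `upper`, `fitted` (point-estimate curve).
#' @export
fr_curve_band <- function(boot, densities, time = NULL) {
  stopifnot(inherits(boot, "fr_boot"))
  if (length(densities) == 0) abort("`densities` must be non-empty.")
  check_nonneg(densities, "densities")
  time <- time %||% mean(boot$fit$data$exposure_time)
  model <- boot$fit$model
  reps <- boot$replicates
  pred <- vapply(seq_len(nrow(reps)), function(i) {
    if (model == "typeII") {
      fr_predict_typeII(densities, time, a = reps$a[i], h = reps$h[i])
    } else {
      fr_predict_flexible(densities, time, b = reps$b[i], q = reps$q[i],
                          h = reps$h[i])
    }
  }, numeric(length(densities)))
  pred <- matrix(pred, nrow = length(densities))
  qs <- t(apply(pred, 1, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE))
  out <- tibble::tibble(
    density = densities, lower = qs[, 1], median = qs[, 2], upper = qs[, 3],
    fitted = predict(boot$fit, densities, time))
  class(out) <- c("fr_band", class(out))
  out
}

#' Compare functional-response parameters between two treatments
#'
#' Fits a pooled model in which each parameter of group B equals the group A
#' value plus a difference term on an indicator variable (difference
#' parameterization), then Wald-tests each difference against zero. This is
#' the standard way to ask whether, say, handling time differs between prey
#' size classes.
#'
#' @param prepared_a,prepared_b Prepared-trials tibbles for the two groups.
#' @param model `"typeII"` or `"flexible"`.
#' @param n_restarts Optimizer restarts for the pooled fit.
#' @param seed Optional integer seed for restart jitter.
#' @return A tibble of class `fr_comparison`: one row per parameter with
#'   `term`, `estimate_a`, `estimate_b`, `difference`, `std.error`,
#'   `statistic`, `p.value`.
#' @examples
#' prepared <- fr_prepare_trials(fr_simulate_trials(seed = 1))
#' a <- dplyr::filter(prepared, prey_size == "small", substrate == "absent")
#' b <- dplyr::filter(prepared, prey_size == "large", substrate == "absent")
#' fr_compare_treatments(a, b, model = "typeII", seed = 1)
#' @export
fr_compare_treatments <- function(prepared_a, prepared_b,
                                  model = c("typeII", "flexible"),
                                  n_restarts = 3, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  fit_a <- fr_fit(prepared_a, model, n_restarts = n_restarts)
  fit_b <- fr_fit(prepared_b, model, n_restarts = n_restarts)
  if (!fit_a$converged || !fit_b$converged) {
    abort(paste("Per-group fits did not both converge; compare parameters",
                "via bootstrap CI overlap instead."))
  }
  par_names <- names(fit_a$estimates)
  k <- length(par_names)
  nll_a <- make_nll(prepared_a, model)
  nll_b <- make_nll(prepared_b, model)
  pos <- par_names != "q"
  # joint parameter vector: group A on the fitting scale, then natural-scale
  # differences (B minus A) so the Wald test applies to them directly
  joint_nll <- function(par) {
    ta <- par[seq_len(k)]
    delta <- par[k + seq_len(k)]
    nat_a <- fitting_to_natural(ta, model, par_names)
    nat_b <- nat_a + delta
    if (any(nat_b[pos] <= 0) || ("q" %in% par_names && nat_b[["q"]] <= -1)) {
      return(Inf)
    }
    nll_a(ta) + nll_b(natural_to_fitting(nat_b, model))
  }
  start <- c(natural_to_fitting(fit_a$estimates, model),
             unname(fit_b$estimates - fit_a$estimates))
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    st <- start
    if (r > 1) st <- st + rnorm(2 * k, 0, 0.2)
    opt <- tryCatch(
      optim(st, joint_nll, method = "Nelder-Mead",
            control = list(maxit = 4000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$convergence != 0) {
    abort("Pooled fit did not converge; compare parameters via bootstrap CI overlap instead.")
  }
  # finite-difference steps scaled to each coordinate: the natural-scale
  # differences can sit at the 1e-3 magnitude of a handling time
  steps <- pmax(abs(best$par) * 1e-3, 1e-6)
  H <- tryCatch(optimHess(best$par, joint_nll, control = list(ndeps = steps)),
                error = function(e) NULL)
  cov_j <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(cov_j) || any(diag(cov_j) <= 0)) {
    abort("Pooled Hessian not invertible; compare parameters via bootstrap CI overlap instead.")
  }
  nat_a <- fitting_to_natural(best$par[seq_len(k)], model, par_names)
  delta <- setNames(best$par[k + seq_len(k)], par_names)
  se_d <- sqrt(diag(cov_j)[k + seq_len(k)])
  z <- delta / se_d
  out <- tibble::tibble(
    term = par_names,
    estimate_a = unname(nat_a),
    estimate_b = unname(nat_a + delta),
    difference = unname(delta),
    std.error = unname(se_d),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))))
  class(out) <- c("fr_comparison", class(out))
  out
}
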