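#' Polynomial logistic regression on proportion of prey consumed
#'
#' Regresses the per-vial proportion eaten on raw powers of the corrected
#' initial density with a binomial GLM (logit link, iteratively reweighted
#' least squares). The signs and significance of the density terms
#' diagnose the response shape: a significant negative first-order term is
#' the hyperbolic (type II) signature, a significant positive first-order
#' followed by a negative second-order term the sigmoidal (type III)
#' signature.
#'
#' @param prepared A prepared-trials tibble (single treatment).
#' @param degree 1 (linear) or 2 (quadratic) in density.
#' @return An object of class `fr_shape`: the glm fit plus a tidy
#'   coefficient table (`term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`) and a `separation` flag.
#' @examples
#' prepared <- fr_prepare_trials(fr_simulate_trials(seed = 1))
#' small <- dplyr::filter(prepared, prey_size == "small", substrate == "absent")
#' fr_shape_test(small, degree = 2)
#' @export
fr_shape_test <- function(prepared, degree = 1) {
  if (!degree %in% c(1, 2)) abort("`degree` must be 1 or 2.")
  dd <- dplyr::filter(prepared, .data$corrected_initial > 0)
  if (dplyr::n_distinct(dd$corrected_initial) < degree + 2) {
    abort("Need at least degree + 2 distinct densities.")
  }
  dd <- dplyr::mutate(dd, not_eaten = .data$corrected_initial - .data$eaten,
                      density = as.numeric(.data$corrected_initial))
  form <- if (degree == 1) {
    cbind(eaten, not_eaten) ~ density
  } else {
    cbind(eaten, not_eaten) ~ density + I(density^2)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dd),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) {
    warn("Possible separation: fitted proportions at 0 or 1; coefficients reported anyway.")
  }
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = c("(Intercept)", "density", "density^2")[seq_len(degree + 1)],
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4])
  structure(list(degree = degree, coefficients = coefs, glm = fit,
                 separation = separation),
            class = "fr_shape")
}

#' @export
print.fr_shape <- function(x, ...) {
  cat(sprintf("<fr_shape> degree-%d logistic regression on proportion eaten\n",
              x$degree))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.fr_shape <- function(x, ...) x$coefficients

#' Classify the functional-response shape from logistic diagnostics
#'
#' Applies the sign-and-significance logic to a linear and a quadratic
#' logistic fit of the same data: the type II pattern is a significant
#' negative linear first-order term; the type III pattern is a significant
#' positive first-order together with a significant negative second-order
#' term in the quadratic fit. Both patterns can co-occur (the quadratic fit
#' can reveal low-density acceleration that the linear fit averages away),
#' in which case both are reported and the final model choice is left to
#' AICc comparison.
#'
#' @param linear An `fr_shape` of degree 1.
#' @param quadratic An `fr_shape` of degree 2 on the same data.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: logical `typeII_pattern` and `typeIII_pattern`
#'   plus a `classification` label (`consistent_typeII`,
#'   `consistent_typeIII`, `both_patterns`, `inconclusive`).
#' @export
fr_classify_shape <- function(linear, quadratic, alpha = 0.05) {
  stopifnot(inherits(linear, "fr_shape"), inherits(quadratic, "fr_shape"))
  if (linear$degree != 1 || quadratic$degree != 2) {
    abort("Pass the degree-1 fit first and the degree-2 fit second.")
  }
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  l1 <- linear$coefficients[linear$coefficients$term == "density", ]
  q1 <- quadratic$coefficients[quadratic$coefficients$term == "density", ]
  q2 <- quadratic$coefficients[quadratic$coefficients$term == "density^2", ]
  typeII <- isTRUE(l1$estimate < 0 && l1$p.value < alpha)
  typeIII <- isTRUE(q1$estimate > 0 && q1$p.value < alpha &&
                      q2$estimate < 0 && q2$p.value < alpha)
  classification <- if (typeII && typeIII) "both_patterns"
    else if (typeIII) "consistent_typeIII"
    else if (typeII) "consistent_typeII"
    else "inconclusive"
  tibble::tibble(typeII_pattern = typeII, typeIII_pattern = typeIII,
                 classification = classification)
}
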