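#' Plot a fitted functional response over the observed counts
#'
#' @param object An `fr_fit` object.
#' @param ... Unused.
#' @return A ggplot: observed prey eaten per vial against corrected initial
#'   density, with the fitted depletion curve.
#' @export
autoplot.fr_fit <- function(object, ...) {
  dd <- object$data
  grid <- seq(0, max(dd$corrected_initial), length.out = 200)
  curve <- tibble::tibble(density = grid,
                          eaten = predict(object, grid))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$corrected_initial,
                                   y = .data$eaten)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$density, y = .data$eaten),
                       linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = "Initial prey density", y = "Prey eaten",
                  title = sprintf("%s functional response", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap confidence band around the fitted response
#'
#' @param object An `fr_band` tibble from [fr_curve_band()].
#' @param ... Unused.
#' @return A ggplot with the pointwise 95% band, bootstrap median and
#'   point-estimate curve.
#' @export
autoplot.fr_band <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$density)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "#2166ac", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linetype = "dashed",
                       colour = "#2166ac") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.8) +
    ggplot2::labs(x = "Initial prey density", y = "Prey eaten",
                  title = "Fitted response with 95% bootstrap band") +
    ggplot2::theme_minimal()
}
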