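#' Principal branch of the Lambert-W function
#'
#' Solves `w * exp(w) = z` for `w` on the principal branch, vectorized over
#' `z`. Only non-negative arguments arise when solving the prey-depletion
#' functional response (the argument is a product of positive rates), so the
#' domain is restricted to `z >= 0`, where W0 is single-valued, non-negative
#' and increasing.
#'
#' Uses Halley's iteration from a log-based starting point; convergence is
#' quadratic-plus and reaches machine precision in a handful of steps across
#' the full double range.
#'
#' @param z Numeric vector, `z >= 0` (NA propagates).
#' @return Numeric vector of the same length with `W0(z)`.
#' @examples
#' lambert_w0(1)           # omega constant, 0.5671433
#' lambert_w0(exp(1))      # exactly 1
#' @export
lambert_w0 <- function(z) {
  if (!is.numeric(z)) abort("`z` must be numeric.")
  w <- rep(NA_real_, length(z))
  ok <- !is.na(z)
  if (any(z[ok] < 0)) abort("lambert_w0() is defined here for z >= 0 only.")
  w[ok & z == 0] <- 0
  idx <- which(ok & z > 0)
  if (length(idx) == 0L) return(w)
  x <- z[idx]
  # start: series-flavoured guess for small z, asymptotic log(z) - log(log(z))
  # for large z; log1p(x) is an adequate bridge in between
  w0 <- ifelse(x > 3, {
    lx <- log(x)
    pmax(lx - log(pmax(lx, 1)), 1e-8)
  }, log1p(x))
  for (i in 1:50) {
    ew <- exp(w0)
    f <- w0 * ew - x
    w1 <- w0 - f / (ew * (w0 + 1) - (w0 + 2) * f / (2 * w0 + 2))
    if (all(abs(w1 - w0) <= 1e-14 * (abs(w1) + 1e-300))) {
      w0 <- w1
      break
    }
    w0 <- w1
  }
  w[idx] <- w0
  w
}

# unchecked scalar/vector W0 for the optimizer hot path: finite z >= 0 only
lamw0_fast <- function(x) {
  w0 <- log1p(x)
  big <- x > 3
  if (any(big)) {
    lx <- log(x[big])
    w0[big] <- pmax(lx - log(lx), 1e-8)
  }
  for (i in 1:50) {
    ew <- exp(w0)
    f <- w0 * ew - x
    w1 <- w0 - f / (ew * (w0 + 1) - (w0 + 2) * f / (2 * w0 + 2))
    delta <- abs(w1 - w0)
    w0 <- w1
    if (all(delta <= 1e-13 * (abs(w1) + 1e-300))) break
  }
  w0
}
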