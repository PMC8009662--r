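#' Wrapped-Gaussian crescent profile
#'
#' Evaluates a unimodal periodic bump on the circle: a Gaussian of width
#' `sigma` wrapped over `2*pi`, normalized so its value at the center is
#' exactly 1. Used both by the synthetic-image generator and by the peak
#' fitter, so that a noise-free generated profile lies exactly on the fitted
#' model manifold.
#'
#' @param delta Angular offset(s) from the bump center, radians (any real
#'   values; the function is `2*pi`-periodic).
#' @param sigma Bump width (radians), `> 0`.
#' @param k_wrap Number of wrap terms on each side; the default (3) is exact
#'   to machine precision for `sigma <= 2*pi`.
#' @return Numeric vector of the same length as `delta`, in `(0, 1]`.
#' @examples
#' wrapped_gaussian(0, 0.3)            # 1 at the center
#' wrapped_gaussian(pi, 0.3)           # essentially 0 opposite the center
#' @export
wrapped_gaussian <- function(delta, sigma, k_wrap = 3L) {
  stopifnot(is.numeric(delta), length(sigma) == 1L, sigma > 0)
  s <- 0
  s0 <- 0
  for (k in -k_wrap:k_wrap) {
    s <- s + exp(-((delta + 2 * pi * k)^2) / (2 * sigma^2))
    s0 <- s0 + exp(-((2 * pi * k)^2) / (2 * sigma^2))
  }
  s / s0
}

#' Wrap an angle to [0, 2*pi)
#' @param theta Angle(s) in radians.
#' @return Angle(s) wrapped into `[0, 2*pi)`.
#' @export
wrap_angle <- function(theta) {
  theta %% (2 * pi)
}

# Smallest signed angular difference a - b, in (-pi, pi].
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Angular midpoints of equal arc portions
#'
#' Midpoint angles of `n` equal portions of the circle, as used for
#' profile positions on an idealized circular cell.
#'
#' @param n Number of portions.
#' @return Numeric vector of `n` midpoint angles in `[0, 2*pi)`.
#' @export
portion_midpoints <- function(n = 63L) {
  (seq_len(n) - 0.5) / n * 2 * pi
}
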