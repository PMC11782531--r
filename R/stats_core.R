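# Probability primitives: scaled (super/sub) Poisson, Skellam, Gaussian
# algebra.  These carry the distributional contracts every other module is
# written against.

#' Gaussian moment pair
#'
#' A light container for the mean and variance of a (approximately) normal
#' random variable, used by the moment-propagation helpers.
#'
#' @param mu mean (counts).
#' @param sigma2 variance (counts^2), must be non-negative.
#' @return an object of class `gaussian_params`.
#' @export
gaussian_params <- function(mu, sigma2) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.numeric(sigma2),
            length(sigma2) == 1)
  if (sigma2 < 0) stop("variance must be non-negative")
  structure(list(mu = mu, sigma2 = sigma2), class = "gaussian_params")
}

#' @export
print.gaussian_params <- function(x, ...) {
  cat(sprintf("N[mu = %g, sigma^2 = %g]\n", x$mu, x$sigma2))
  invisible(x)
}

#' Scaled-Poisson (super-/sub-Poisson) probability mass
#'
#' Density of `g * Poisson(s_hat / g)` evaluated on the count grid, the
#' distribution of a Poisson-distributed number of primary events each
#' producing on average `g` counts.  `g > 1` gives a super-Poisson
#' (variance `g * s_hat` above the mean `s_hat`), `g < 1` a sub-Poisson,
#' and `g = 1` recovers the true Poisson distribution.  For fractional `g`
#' the factorial is replaced by the gamma function and the mass is
#' renormalized numerically over the integer count grid, as the analytic
#' expression is then only an approximate density.
#'
#' @param n count value(s), non-negative.
#' @param s_hat expected counts, non-negative.
#' @param g counts per primary event, positive.
#' @param renormalize renormalize over the integer count grid so the masses
#'   sum to one (default `TRUE`).  With `FALSE` the raw analytic expression
#'   is returned.
#' @param grid_max upper end of the integer evaluation grid used for
#'   renormalization; defaults to a high quantile of the underlying Poisson.
#' @return probability mass at `n`.
#' @export
dscaled_pois <- function(n, s_hat, g, renormalize = TRUE, grid_max = NULL) {
  if (any(n < 0)) stop("counts must be non-negative")
  if (!is.numeric(g) || g <= 0) stop("gain g must be positive")
  if (s_hat < 0) stop("expected counts must be non-negative")
  raw <- function(x) {
    if (s_hat == 0) return(as.numeric(x == 0))
    exp((x / g) * log(s_hat / g) - lgamma(x / g + 1) - s_hat / g)
  }
  v <- raw(n)
  if (!renormalize) return(v)
  if (is.null(grid_max)) {
    grid_max <- ceiling(g * (stats::qpois(1 - 1e-12, s_hat / g) + 10) + 10)
  }
  z <- sum(raw(seq(0, grid_max)))
  v / z
}

#' Draw from the scaled-Poisson distribution
#'
#' Sampling uses the defining construction `g * Poisson(s_hat / g)` exactly
#' (not inverse-CDF on the renormalized grid mass), so the sample mean is
#' `s_hat` and the sample variance `g * s_hat`.
#'
#' @param n number of draws.
#' @inheritParams dscaled_pois
#' @export
rscaled_pois <- function(n, s_hat, g) {
  if (g <= 0) stop("gain g must be positive")
  if (s_hat < 0) stop("expected counts must be non-negative")
  g * stats::rpois(n, s_hat / g)
}

#' Skellam (Poisson difference) probability mass
#'
#' Distribution of the difference of two independent Poisson counts with
#' expectations `s1` and `s2`; mean `s1 - s2`, variance `s1 + s2`.  The
#' Bessel function is evaluated in exponentially-scaled form to avoid
#' overflow at large arguments.  `s2 = 0` (or `s1 = 0`) falls back to the
#' (mirrored) Poisson limit.
#'
#' @param n integer count difference(s).
#' @param s1,s2 expected counts of the two components, non-negative.
#' @return probability mass at `n`.
#' @export
dskellam <- function(n, s1, s2) {
  stopifnot(s1 >= 0, s2 >= 0)
  if (any(n != round(n))) stop("Skellam mass is defined on integers")
  if (s2 == 0 || s1 == 0) {
    out <- numeric(length(n))
    if (s2 == 0) out[n >= 0] <- stats::dpois(n[n >= 0], s1)
    else out[n <= 0] <- stats::dpois(-n[n <= 0], s2)
    return(out)
  }
  x <- 2 * sqrt(s1 * s2)
  # besselI(..., expon.scaled = TRUE) returns I(x) * exp(-x)
  exp(-(s1 + s2) + x + (n / 2) * log(s1 / s2)) *
    besselI(x, abs(n), expon.scaled = TRUE)
}

#' @rdname dskellam
#' @param ndraw number of draws.
#' @export
rskellam <- function(ndraw, s1, s2) {
  stats::rpois(ndraw, s1) - stats::rpois(ndraw, s2)
}

#' Moments of a product of independent random variables
#'
#' For independent X and Y, `E[XY] = E[X] E[Y]` and
#' `Var(XY) = (sx^2 + mx^2)(sy^2 + my^2) - mx^2 my^2`.  The returned pair is
#' a moment summary; the product distribution itself is generally not
#' normal.
#'
#' @param a,b `gaussian_params` moment pairs of the two factors.
#' @return a `gaussian_params` with the product's mean and variance.
#' @export
gaussian_product_moments <- function(a, b) {
  stopifnot(inherits(a, "gaussian_params"), inherits(b, "gaussian_params"))
  mu <- a$mu * b$mu
  s2 <- (a$sigma2 + a$mu^2) * (b$sigma2 + b$mu^2) - a$mu^2 * b$mu^2
  gaussian_params(mu, s2)
}

#' Normal approximation to the reciprocal of a narrow Gaussian
#'
#' If X is approximately `N[mu, sigma^2]` with `mu >> sigma`, then `1/X` is
#' approximately `N[1/mu, sigma^2 / mu^4]`.  A warning is issued when
#' `mu / sigma < 10`, where the approximation degrades.
#'
#' @param a a `gaussian_params` pair.
#' @return a `gaussian_params` pair for the reciprocal.
#' @export
inverse_gaussian_approx <- function(a) {
  stopifnot(inherits(a, "gaussian_params"))
  if (a$mu == 0) stop("reciprocal of a zero-mean variable is undefined")
  if (a$sigma2 > 0 && abs(a$mu) / sqrt(a$sigma2) < 10) {
    warning("mu/sigma < 10: normal approximation to the reciprocal is poor")
  }
  gaussian_params(1 / a$mu, a$sigma2 / a$mu^4)
}
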