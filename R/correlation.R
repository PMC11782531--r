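# Lag-space machinery: autocovariance via the Wiener-Khinchin theorem,
# Pearson coefficient fields, the smoothing factors beta_corr and beta_conv,
# coefficient propagation under binning, and PSF reconstruction.
#
# Conventions (used throughout the package):
#   * lag fields are stored centred with odd dimensions; rows index the
#     vertical lag m in [-(M-1), M-1], columns the horizontal lag n in
#     [-(N-1), N-1], with lag (0, 0) at the central element;
#   * estimation uses the circular (periodogram) estimator implied by the
#     FFT, and all synthetic-data oracles therefore use circular
#     convolution;
#   * kernels are stored on the same centred grids.

#' Convolution / correlation kernels
#'
#' A centred, odd-dimension kernel with an explicit normalization
#' convention: `"sum"` kernels sum to one (probability kernels such as the
#' detector PSF), `"height"` kernels have maximum one (beam-disc kernels,
#' whose absolute scale carries no gain).
#'
#' @param omega numeric matrix (or vector for 1D kernels) with odd
#'   dimensions; entries must be non-negative.
#' @param normalization `"sum"` or `"height"`.
#' @return an object of class `ccd_kernel` with elements `omega` and
#'   `normalization`.
#' @export
ccd_kernel <- function(omega, normalization = c("sum", "height")) {
  normalization <- match.arg(normalization)
  if (is.vector(omega)) omega <- matrix(omega, nrow = 1)
  if (any(omega < 0)) stop("kernel entries must be non-negative")
  if (nrow(omega) %% 2L == 0L || ncol(omega) %% 2L == 0L)
    stop("kernels must have odd dimensions (centred)")
  s <- sum(omega)
  if (s <= 0) stop("kernel must have positive mass")
  omega <- switch(normalization, sum = omega / s, height = omega / max(omega))
  structure(list(omega = omega, normalization = normalization),
            class = "ccd_kernel")
}

#' @export
print.ccd_kernel <- function(x, ...) {
  cat(sprintf("<ccd_kernel %dx%d, %s-normalized, central mass %.4g>\n",
              nrow(x$omega), ncol(x$omega), x$normalization,
              x$omega[(nrow(x$omega) + 1) %/% 2, (ncol(x$omega) + 1) %/% 2]))
  invisible(x)
}

#' Discrete Gaussian kernel
#'
#' @param sigma standard deviation in pixels (`0` gives a delta kernel).
#' @param radius half-width of the grid; defaults to `ceiling(5 * sigma)`.
#' @param normalization passed to [ccd_kernel()].
#' @param dim build a 2D (default) or 1D kernel.
#' @return a `ccd_kernel`.
#' @export
gaussian_kernel <- function(sigma, radius = NULL,
                            normalization = c("sum", "height"), dim = 2L) {
  normalization <- match.arg(normalization)
  if (sigma < 0) stop("sigma must be non-negative")
  if (is.null(radius)) radius <- max(1L, ceiling(5 * sigma))
  idx <- seq(-radius, radius)
  if (sigma == 0) {
    v <- as.numeric(idx == 0)
  } else {
    v <- exp(-idx^2 / (2 * sigma^2))
  }
  omega <- if (dim == 2L) outer(v, v) else matrix(v, nrow = 1)
  ccd_kernel(omega, normalization)
}

#' @rdname gaussian_kernel
#' @export
delta_kernel <- function(dim = 2L) {
  omega <- if (dim == 2L) matrix(1, 1, 1) else matrix(1, 1, 1)
  ccd_kernel(omega, "sum")
}

new_lag_field <- function(mat, source_shape, class) {
  stopifnot(nrow(mat) %% 2L == 1L, ncol(mat) %% 2L == 1L)
  structure(list(field = mat,
                 center = c((nrow(mat) + 1L) %/% 2L, (ncol(mat) + 1L) %/% 2L),
                 source_shape = source_shape),
            class = class)
}

#' Autocovariance and Pearson lag fields
#'
#' `acov_field()` and `pearson_field()` wrap centred lag-indexed matrices
#' (vertical lag along rows, horizontal lag along columns, lag (0,0) at the
#' centre).  They are produced by [autocovariance_wk()] /
#' [pearson_normalize()] but can also be built directly, e.g. from an
#' analytic kernel via [pearson_from_kernel()].
#'
#' @param mat centred odd-dimension matrix of lag values.
#' @param source_shape dimensions `c(M, N)` of the image the field refers
#'   to (used by [beta_corr()] defaults); may be `NULL` for analytic fields.
#' @return an object of class `ccd_acov` or `ccd_pearson`.
#' @export
acov_field <- function(mat, source_shape = NULL) {
  new_lag_field(mat, source_shape, "ccd_acov")
}

#' @rdname acov_field
#' @export
pearson_field <- function(mat, source_shape = NULL) {
  f <- new_lag_field(mat, source_shape, "ccd_pearson")
  cv <- f$field[f$center[1], f$center[2]]
  if (abs(cv - 1) > 1e-8)
    stop("central Pearson coefficient must be 1")
  f
}

#' @export
print.ccd_acov <- function(x, ...) {
  cat(sprintf("<autocovariance field %dx%d, K[0,0] = %.6g>\n",
              nrow(x$field), ncol(x$field),
              x$field[x$center[1], x$center[2]]))
  invisible(x)
}

#' @export
print.ccd_pearson <- function(x, ...) {
  cat(sprintf("<Pearson field %dx%d, sum(rho) = %.6g>\n",
              nrow(x$field), ncol(x$field), sum(x$field)))
  invisible(x)
}

#' Autocovariance of an image via the Wiener-Khinchin theorem
#'
#' The autocovariance function K and the power spectral density form a
#' Fourier-transform pair.  The mean is subtracted, the periodogram
#' `|F[image - mean]|^2 / (M N)` is inverted, and the circular lags are
#' unfolded onto the centred `(2M-1) x (2N-1)` grid.  `K[0,0]` equals the
#' mean squared deviation of the image.  Note this is the circular
#' estimator: lag (m, n) and lag (m - M, n - N) share one estimate, and the
#' coefficients of a single frame sum to zero over the distinct circular
#' lags, which biases large-lag entries slightly negative.
#'
#' @param image numeric matrix of counts (at least 2 x 2, finite values).
#' @return a `ccd_acov` field.
#' @export
autocovariance_wk <- function(image) {
  if (inherits(image, "ccd_frame")) image <- image$data
  if (!is.matrix(image) || nrow(image) < 2 || ncol(image) < 2)
    stop("image must be a matrix with at least 2x2 pixels")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  m <- nrow(image); n <- ncol(image)
  d <- image - mean(image)
  psd <- Mod(stats::fft(d))^2 / (m * n)
  kc <- Re(stats::fft(psd, inverse = TRUE)) / (m * n)
  rows <- (seq(-(m - 1L), m - 1L) %% m) + 1L
  cols <- (seq(-(n - 1L), n - 1L) %% n) + 1L
  acov_field(kc[rows, cols, drop = FALSE], c(m, n))
}

#' Pearson correlation coefficients from an autocovariance field
#'
#' Normalizes by the central element so that `rho[0,0] = 1`.
#'
#' @param K a `ccd_acov` field with positive central element.
#' @return a `ccd_pearson` field.
#' @export
pearson_normalize <- function(K) {
  stopifnot(inherits(K, "ccd_acov"))
  k0 <- K$field[K$center[1], K$center[2]]
  if (k0 <= 0) stop("degenerate field: K[0,0] must be positive")
  pearson_field(K$field / k0, K$source_shape)
}

#' Crop or zero-pad a centred lag matrix to given radii
#'
#' @param mat centred odd-dimension matrix.
#' @param rv,rh target vertical/horizontal radii.
#' @return a `(2 rv + 1) x (2 rh + 1)` matrix.
#' @export
resize_centred <- function(mat, rv, rh) {
  cv <- (nrow(mat) + 1L) %/% 2L
  ch <- (ncol(mat) + 1L) %/% 2L
  out <- matrix(0, 2L * rv + 1L, 2L * rh + 1L)
  sv <- min(rv, cv - 1L); sh <- min(rh, ch - 1L)
  out[(rv + 1L) + seq(-sv, sv), (rh + 1L) + seq(-sh, sh)] <-
    mat[cv + seq(-sv, sv), ch + seq(-sh, sh), drop = FALSE]
  out
}

#' Finite-frame correlation factor beta_corr
#'
#' The expected sample variance of a single M x N frame relates to the true
#' per-pixel variance through
#' `beta_corr = MN/(MN-1) * (1 - (MN)^-2 * sum (M-|m|)(N-|n|) rho[m,n])`,
#' which lies in `[0, 2]`: 1 for uncorrelated noise, below 1 for
#' correlation, exactly 2 in the total anti-correlation limit (all
#' off-centre coefficients -1), and 0 for total correlation.
#'
#' @param rho a `ccd_pearson` field (zero-padded if it covers fewer lags
#'   than `+/-(M-1)`, `+/-(N-1)`).
#' @param M,N frame dimensions (rows, columns); default to the field's
#'   source shape.
#' @return the dimensionless factor.
#' @export
beta_corr <- function(rho, M = NULL, N = NULL) {
  stopifnot(inherits(rho, "ccd_pearson"))
  if (is.null(M)) M <- rho$source_shape[1]
  if (is.null(N)) N <- rho$source_shape[2]
  if (is.null(M) || is.null(N)) stop("frame dimensions M, N required")
  if (M * N <= 1) stop("need more than one pixel")
  r <- resize_centred(rho$field, M - 1L, N - 1L)
  wv <- M - abs(seq(-(M - 1L), M - 1L))
  wh <- N - abs(seq(-(N - 1L), N - 1L))
  s <- as.numeric(wv %*% r %*% wh)
  (M * N) / (M * N - 1) * (1 - s / (M * N)^2)
}

#' Convolution smoothing factor beta_conv
#'
#' The reduction of Poisson variance by convolution with a kernel equals
#' the central element of the kernel's autocorrelation, which is the
#' reciprocal of the sum of the Pearson coefficients:
#' `beta_conv = (sum rho)^-1`, in (0, 1] for non-negative fields.
#'
#' @param rho a `ccd_pearson` field.
#' @return the dimensionless smoothing factor.
#' @export
beta_conv <- function(rho) {
  stopifnot(inherits(rho, "ccd_pearson"))
  s <- sum(rho$field)
  if (s <= 0)
    stop("sum of Pearson coefficients is non-positive; ",
         "stationarity-degenerate field (estimated single-frame fields sum ",
         "to ~0 by construction - clip with clip_negative_field() first)")
  1 / s
}

#' Pearson coefficients after binning
#'
#' Summing H x V pixel blocks adds `2w - 1` coefficients per direction:
#' `rho00_star = sum (H-|h|)(V-|v|) rho[h, v]` becomes the variance
#' multiplier of the binned system, and the binned coefficients are
#' `rho_bin[m, n] = sum (H-|h|)(V-|v|) rho[Vm+v, Hn+h] / rho00_star`.
#' Lags outside the stored field are treated as zero.
#'
#' @param rho a `ccd_pearson` field.
#' @param H horizontal binning value (columns per block), >= 1.
#' @param V vertical binning value (rows per block), >= 1.
#' @return a list with `rho_bin` (a `ccd_pearson` on the binned lag grid)
#'   and `rho00_star` (the variance multiplier).
#' @export
bin_pearson <- function(rho, H = 1L, V = 1L) {
  stopifnot(inherits(rho, "ccd_pearson"), H >= 1, V >= 1)
  H <- as.integer(H); V <- as.integer(V)
  f <- rho$field
  rv <- (nrow(f) - 1L) %/% 2L
  rh <- (ncol(f) - 1L) %/% 2L
  cv <- rv + 1L; ch <- rh + 1L
  rv2 <- rv %/% V; rh2 <- rh %/% H
  get <- function(i, j) {
    ok <- abs(i) <= rv & abs(j) <= rh
    v <- numeric(length(i))
    v[ok] <- f[cbind(cv + i[ok], ch + j[ok])]
    v
  }
  hh <- seq(-(H - 1L), H - 1L)
  vv <- seq(-(V - 1L), V - 1L)
  wt <- outer(V - abs(vv), H - abs(hh))
  binned_at <- function(m, n) {
    ij <- expand.grid(v = vv, h = hh)
    sum(wt * matrix(get(V * m + ij$v, H * n + ij$h), nrow = length(vv)))
  }
  out <- matrix(0, 2L * rv2 + 1L, 2L * rh2 + 1L)
  for (m in seq(-rv2, rv2)) for (n in seq(-rh2, rh2)) {
    out[rv2 + 1L + m, rh2 + 1L + n] <- binned_at(m, n)
  }
  r0 <- out[rv2 + 1L, rh2 + 1L]
  if (r0 <= 0) stop("degenerate binning: rho00_star must be positive")
  src <- rho$source_shape
  if (!is.null(src)) src <- c(src[1] %/% V, src[2] %/% H)
  list(rho_bin = pearson_field(out / r0, src), rho00_star = r0)
}

#' Set negative entries of an autocovariance field to zero
#'
#' The K+ operation used when rebuilding noise budgets from estimated
#' fields: the circular estimator forces the coefficients of one frame to
#' sum to zero, leaking small negative entries into the tails, which are
#' clipped before coefficient sums are taken.  Applied only where the
#' estimation procedure calls for it, never silently.
#'
#' @param K a `ccd_acov` or `ccd_pearson` field.
#' @return the field with negative entries set to zero.
#' @export
clip_negative_field <- function(K) {
  K$field <- clip_negative(K$field)
  K
}

#' Reconstruct the convolution kernel from a Pearson field
#'
#' The detector PSF hides in the noise correlations: since the
#' autocorrelation of convolved noise takes the shape of the kernel
#' convolved with itself, the kernel is the inverse Fourier transform of
#' the square root of the PSD, `Omega = F^-1[(F[rho])^(1/2)]`.  Negative
#' Fourier magnitudes (from estimator noise) are clipped to zero and the
#' clipped mass is recorded; in strict mode more than `max_clip` clipped
#' mass escalates to an error.
#'
#' @param rho a `ccd_pearson` field.
#' @param strict error (rather than warn) when the clipped spectral mass
#'   exceeds `max_clip`.
#' @param max_clip tolerated fraction of clipped spectral mass (default 5%).
#' @return a sum-normalized `ccd_kernel`; attribute `"clipped_mass"` holds
#'   the clipped spectral fraction.
#' @export
psf_from_pearson <- function(rho, strict = FALSE, max_clip = 0.05) {
  stopifnot(inherits(rho, "ccd_pearson"))
  f <- rho$field
  Fr <- Re(stats::fft(to_origin(f)))
  neg <- sum(pmax(-Fr, 0))
  tot <- sum(abs(Fr))
  clipped <- if (tot > 0) neg / tot else 0
  if (clipped > max_clip) {
    msg <- sprintf("clipped %.1f%% of spectral mass (limit %.1f%%)",
                   100 * clipped, 100 * max_clip)
    if (strict) stop(msg) else warning(msg)
  }
  Fr[Fr < 0] <- 0
  om <- Re(stats::fft(sqrt(Fr), inverse = TRUE)) / length(Fr)
  om <- to_center(om)
  om[om < 0] <- 0
  k <- ccd_kernel(om, "sum")
  attr(k, "clipped_mass") <- clipped
  k
}

#' Pearson field implied by a convolution kernel
#'
#' Builds the analytic field `rho = Omega (x) Omega / [Omega (x) Omega]_00`
#' on a centred grid, the correlation structure that convolving white noise
#' with `Omega` imprints.
#'
#' @param kernel a `ccd_kernel`.
#' @param radius half-width of the output lag grid; defaults to twice the
#'   kernel half-width.
#' @param source_shape optional frame shape recorded on the field.
#' @return a `ccd_pearson` field.
#' @export
pearson_from_kernel <- function(kernel, radius = NULL, source_shape = NULL) {
  stopifnot(inherits(kernel, "ccd_kernel"))
  om <- kernel$omega
  rv <- (nrow(om) - 1L) %/% 2L
  rh <- (ncol(om) - 1L) %/% 2L
  if (is.null(radius)) radius <- 2L * max(rv, rh, 1L)
  m <- 4L * radius + 1L
  grid_r <- if (nrow(om) == 1L) 0L else 2L * radius
  grid_c <- 2L * radius
  big_m <- 2L * grid_r + 1L; big_n <- 2L * grid_c + 1L
  delta <- matrix(0, big_m, big_n)
  delta[grid_r + 1L, grid_c + 1L] <- 1
  blurred <- circ_convolve(delta, om)
  ac <- circ_convolve(blurred, blurred[rev(seq_len(big_m)), rev(seq_len(big_n)),
                                       drop = FALSE])
  ac <- ac / ac[grid_r + 1L, grid_c + 1L]
  keep_r <- if (grid_r == 0L) 0L else radius
  out <- resize_centred(ac, keep_r, radius)
  pearson_field(out, source_shape)
}
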