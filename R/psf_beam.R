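# Separating beam-induced long-range correlation from the detector PSF and
# reconstructing both.

#' Fit the beam-correlation surface of a Pearson field
#'
#' Correlated beam electrons imprint a broad, low-amplitude component on
#' the Pearson coefficients of flat frames.  An offsetted 2D Gaussian
#' `offset + A exp(-(m^2+n^2)/(2 sigma^2))` is least-squares fitted to the
#' field, omitting the core region (inside `exclusion_radius`) where the
#' detector PSF dominates.  The fitted amplitude maps to the
#' `2 p (1 - p)` beam term; the quadratic `p^2` term is absorbed into the
#' constant offset.
#'
#' @param rho a `ccd_pearson` field.
#' @param exclusion_radius lags excluded around the centre (pixels);
#'   default 10, an order of magnitude above a typical 2 px core FWHM.
#' @return an object of class `beam_correlation_fit` with `amplitude`,
#'   `sigma_tem`, `offset`, `p_hat` and `rho_core_sum`.
#' @export
fit_beam_correlation <- function(rho, exclusion_radius = 10) {
  stopifnot(inherits(rho, "ccd_pearson"))
  f <- rho$field
  rv <- (nrow(f) - 1L) %/% 2L; rh <- (ncol(f) - 1L) %/% 2L
  if (exclusion_radius >= min(rv, rh))
    stop("field smaller than the exclusion region")
  r2 <- wrapped_lag_r2(f, rho$source_shape)
  sel <- r2 > exclusion_radius^2
  df <- data.frame(y = f[sel], r2 = r2[sel])
  rmax <- sqrt(max(df$r2))
  off0 <- stats::median(df$y[df$r2 > (0.6 * rmax)^2])
  near <- df$r2 <= (2 * exclusion_radius)^2
  a0 <- max(stats::median(df$y[near]) - off0, 1e-8)
  s0 <- rmax / 4
  fit <- minpack.lm::nlsLM(
    y ~ off + A * exp(-r2 / (2 * s^2)), data = df,
    start = list(off = off0, A = a0, s = s0),
    lower = c(-Inf, 0, 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  surface <- cf["off"] + cf["A"] * exp(-r2 / (2 * cf["s"]^2))
  core_sum <- sum((f - surface)[!sel])
  p_hat <- tryCatch(
    estimate_p_from_amplitude(unname(cf["A"]), core_sum),
    error = function(e) NA_real_)
  structure(list(amplitude = unname(cf["A"]),
                 sigma_tem = unname(cf["s"]),
                 offset = unname(cf["off"]),
                 p_hat = p_hat, rho_core_sum = core_sum,
                 exclusion_radius = exclusion_radius),
            class = "beam_correlation_fit")
}

#' @export
print.beam_correlation_fit <- function(x, ...) {
  cat(sprintf(
    "<beam_correlation_fit A = %.4g, sigma_TEM = %.4g px, offset = %.4g, p = %.4g>\n",
    x$amplitude, x$sigma_tem, x$offset, x$p_hat))
  invisible(x)
}

# Squared lag distance on the centred grid, wrapped by the circular
# topology of the periodogram estimator: an unfolded lag m beyond half the
# source dimension duplicates the circular lag m - M, so structure there
# must be measured (and subtracted) at the wrapped distance.
wrapped_lag_r2 <- function(f, source_shape = NULL) {
  rv <- (nrow(f) - 1L) %/% 2L; rh <- (ncol(f) - 1L) %/% 2L
  m_lag <- abs(seq(-rv, rv)); n_lag <- abs(seq(-rh, rh))
  if (!is.null(source_shape)) {
    m_lag <- pmin(m_lag, source_shape[1] - m_lag)
    n_lag <- pmin(n_lag, source_shape[2] - n_lag)
  }
  outer(m_lag^2, n_lag^2, `+`)
}

estimate_p_from_amplitude <- function(amplitude, rho_core_sum) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (rho_core_sum <= 0) stop("core coefficient sum must be positive")
  disc <- 1 - 2 * amplitude / rho_core_sum
  if (disc < -0.02) stop("no real root in [0, 0.5): amplitude too large")
  if (disc < 0) {
    warning("amplitude at the 2p(1-p) maximum: returning the p = 0.5 boundary")
    return(0.5)
  }
  (1 - sqrt(disc)) / 2
}

#' Correlated-electron probability from a beam-correlation fit
#'
#' Solves `amplitude = 2 p (1 - p) * h` for the smaller root `p` in
#' `[0, 0.5)`, where `h` is the height-one core factor (the coefficient
#' sum of the detector-PSF core, `(sum Omega_d*)^2 / sum Omega_d*^2`).
#'
#' @param beam_fit a `beam_correlation_fit`.
#' @param rho_core_sum the core coefficient sum `h`; defaults to the value
#'   measured during the fit.
#' @return the probability `p`.
#' @export
estimate_p <- function(beam_fit, rho_core_sum = NULL) {
  stopifnot(inherits(beam_fit, "beam_correlation_fit"))
  if (is.null(rho_core_sum)) rho_core_sum <- beam_fit$rho_core_sum
  estimate_p_from_amplitude(beam_fit$amplitude, rho_core_sum)
}

#' Full width at half maximum of a 2D kernel
#'
#' From the average of the central horizontal and vertical profiles, with
#' linear interpolation of the half-maximum crossings.
#'
#' @param kernel a `ccd_kernel`.
#' @return FWHM in pixels.
#' @export
kernel_fwhm <- function(kernel) {
  om <- kernel$omega
  cv <- (nrow(om) + 1L) %/% 2L; ch <- (ncol(om) + 1L) %/% 2L
  prof <- if (nrow(om) == 1L) om[1, ] else (om[cv, ] + om[, ch]) / 2
  ctr <- which.max(prof)
  half <- prof[ctr] / 2
  cross <- function(p) {
    i <- which(p < half)[1]
    if (is.na(i) || i == 1L) return(NA_real_)
    (i - 1) + (p[i - 1] - half) / (p[i - 1] - p[i])
  }
  right <- cross(prof[ctr:length(prof)])
  left <- cross(rev(prof[1:ctr]))
  if (is.na(left) || is.na(right)) return(NA_real_)
  (left - 1) + (right - 1)
}

#' Reconstruct the detector PSF with beam-correlation subtraction
#'
#' The long-range beam correlation must be subtracted from the signal
#' autocovariance before inverting, otherwise its tails collapse the
#' reconstructed kernel's central mass.  The fitted Gaussian surface
#' (scaled to autocovariance units) is removed and the kernel obtained as
#' the inverse Fourier transform of the square root,
#' `Omega_d* = F^-1[(K_sig - G_corr)^(1/2)]`, recentred, clipped and
#' sum-normalized.
#'
#' @param K_sig the signal `ccd_acov` field (as from
#'   [estimate_smoothed_gain()]).
#' @param beam_fit a `beam_correlation_fit` obtained from the normalized
#'   version of the same field, or `NULL` to skip the subtraction.
#' @return list with `kernel` (sum-normalized `ccd_kernel`) and `fwhm`
#'   (pixels).
#' @export
detector_psf <- function(K_sig, beam_fit = NULL) {
  stopifnot(inherits(K_sig, "ccd_acov"))
  f <- K_sig$field
  k0 <- f[K_sig$center[1], K_sig$center[2]]
  if (!is.null(beam_fit)) {
    stopifnot(inherits(beam_fit, "beam_correlation_fit"))
    rv <- (nrow(f) - 1L) %/% 2L; rh <- (ncol(f) - 1L) %/% 2L
    r2 <- wrapped_lag_r2(f, K_sig$source_shape)
    surface <- k0 * (beam_fit$offset +
                       beam_fit$amplitude *
                       exp(-r2 / (2 * beam_fit$sigma_tem^2)))
    if (surface[rv + 1L, rh + 1L] >= k0)
      stop("fitted beam surface exceeds the central autocovariance element")
    f <- f - surface
  }
  Fr <- Re(stats::fft(to_origin(f)))
  Fr[Fr < 0] <- 0
  om <- to_center(Re(stats::fft(sqrt(Fr), inverse = TRUE)) / length(Fr))
  om[om < 0] <- 0
  kern <- ccd_kernel(om, "sum")
  list(kernel = kern, fwhm = kernel_fwhm(kern))
}
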