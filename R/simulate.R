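# Forward simulator of the image-formation chain: correlated/uncorrelated
# Poisson beam electrons, detector PSF blur, fixed-pattern gain, optional
# brighter-fatter blur, dark current, polynomial non-linearity, and
# per-quadrant read-out/row/offset noise.

#' Detector frames
#'
#' A 2D grid of counts with its exposure time, kind and seed record.
#' Simulated frames additionally carry a `truth` list with the realized
#' ground-truth quantities (mean electron/count signal, per-quadrant row
#' offsets) used by recovery tests.
#'
#' @param data numeric matrix of counts.
#' @param t_acq acquisition time in seconds.
#' @param kind `"signal"`, `"dark"` or a processing-derived kind.
#' @param seed seed record (may be `NA`).
#' @param truth optional list of ground-truth metadata.
#' @return an object of class `ccd_frame`.
#' @export
ccd_frame <- function(data, t_acq, kind = "signal", seed = NA_integer_,
                      truth = NULL) {
  stopifnot(is.matrix(data), is.na(t_acq) || t_acq >= 0)
  structure(list(data = data, t_acq = t_acq, kind = kind, seed = seed,
                 truth = truth),
            class = "ccd_frame")
}

#' @export
print.ccd_frame <- function(x, ...) {
  cat(sprintf("<ccd_frame %dx%d, kind = %s, t_acq = %.3gs, mean = %.4g>\n",
              nrow(x$data), ncol(x$data), x$kind, x$t_acq, mean(x$data)))
  invisible(x)
}

# Effective Gaussian width of a height-one beam-disc kernel, from its
# total mass (a height-one 2D Gaussian has mass 2 pi sigma^2).
beam_sigma_tem <- function(om_tem) {
  sqrt(sum(om_tem) / (2 * pi))
}

# Gaussian blur width realizing a brighter-fatter smoothing factor on top
# of the detector PSF: the blur is chosen so that the variance of the
# PSF-correlated signal drops by exactly beta_bf,
# sum((psf (x) blur)^2) / sum(psf^2) = beta_bf.  (The first-order
# off-centre-mass relation holds for white noise only; on an already
# smoothed signal the same blur removes far more variance.)
bf_sigma_forward <- function(beta_bf, psf) {
  if (beta_bf >= 1) return(0)
  base <- sum(psf$omega^2)
  ratio <- function(sig) {
    b <- gaussian_kernel(sig, radius = 3L)$omega
    tot <- circ_convolve(embed_kernel(psf$omega, 21L, 21L), b)
    sum(tot^2) / base
  }
  if (ratio(1.5) > beta_bf) return(1.5)
  stats::uniroot(function(s) ratio(s) - beta_bf, c(1e-3, 1.5),
                 tol = 1e-9)$root
}

# Forward gain non-linearity: the charge-well counts are distorted by the
# exact inverse of the linearization family, so that the polynomial
# correction with the generating coefficients restores linearity exactly.
# With accumulated pre-offset counts P and read-out offset `off`, the
# distorted value d solves  d * (d+off) / q(d+off) = P,  where
# q(u) = u - x1 - x2 u^2 - x3 u^3 is the correction denominator evaluated
# at the offset-inclusive level (saturation acts on total accumulated
# charge).  Solved by vectorized Newton iteration.
distort_counts <- function(pre, off, nonlin, iters = 6L) {
  x1 <- nonlin[1]; x2 <- nonlin[2]; x3 <- nonlin[3]
  d <- pre
  for (i in seq_len(iters)) {
    u <- d + off
    q <- u - x1 - x2 * u^2 - x3 * u^3
    if (min(q) <= 0) stop("non-linearity drives counts out of range")
    qp <- 1 - 2 * x2 * u - 3 * x3 * u^2
    h <- d * u / q
    hp <- (u * q + d * q - d * u * qp) / q^2
    d <- d - (h - pre) / hp
  }
  d
}

# Per-quadrant read-out stage: integer row-bias offsets (the bias steps of
# the ADC are integer-valued), per-pixel Gaussian read noise, and the
# read-out offset.  Returns the noise frame in counts and the realized
# integer offsets.
readout_noise <- function(det, seed) {
  set.seed(seed)
  q <- quadrant_ranges(det$shape)
  out <- matrix(0, det$shape[1], det$shape[2])
  offsets <- list()
  for (nm in names(q)) {
    rows <- q[[nm]]$rows; cols <- q[[nm]]$cols
    roff <- round(stats::rnorm(length(rows), 0, det$row_sigma[nm]))
    read <- matrix(stats::rnorm(length(rows) * length(cols), 0,
                                det$read_sigma[nm]),
                   length(rows), length(cols))
    out[rows, cols] <- det$read_offset[nm] + roff + read
    offsets[[nm]] <- roff
  }
  list(noise = det$g_c * out, row_offsets = offsets)
}

#' Simulate a signal frame
#'
#' Runs the image-formation chain: (1) beam electrons are drawn as a
#' Poisson field; correlated electrons (probability `p`) are spread by the
#' height-one beam kernel acting on the *realized* field, which imprints
#' the `2 p (1-p) Omega_TEM*` term on the Pearson coefficients; (2) the
#' realization is convolved with the detector PSF, scaled by the gain and
#' modulated by the fixed-pattern gain map; (3) an optional
#' signal-dependent brighter-fatter blur is applied (count-conserving);
#' (4) Poisson dark counts accumulate at `dark_rate * t_acq`; (5) the
#' accumulated charge-well counts are distorted by the forward
#' non-linearity `S - x1 - x2 S^2 - x3 S^3`; (6) per-quadrant read-out
#' noise, integer row-bias offsets and the read-out offset are added.
#' All convolutions are circular, consistent with the periodogram
#' estimators of the calibration side.
#'
#' @param det a [detector_model()].
#' @param beam a [beam_model()].
#' @param t_acq acquisition time (s).
#' @param seed master seed; expands deterministically to per-stage streams.
#' @return a `ccd_frame` of kind `"signal"`.
#' @export
simulate_frame <- function(det, beam, t_acq, seed) {
  stopifnot(inherits(det, "detector_model"), inherits(beam, "beam_model"),
            t_acq >= 0)
  m <- det$shape[1]; n <- det$shape[2]
  mu_src <- beam$s_src * t_acq
  if (length(mu_src) == 1) mu_src <- matrix(mu_src, m, n)
  om_tem <- beam$omega_tem$omega
  broad <- beam$p > 0 && length(om_tem) > 1
  mu_el <- if (length(om_tem) > 1) circ_convolve(mu_src, om_tem) else mu_src

  set.seed(derive_seed(seed, 1L))
  e <- matrix(stats::rpois(m * n, mu_el), m, n)
  if (broad) {
    # beam bunching: zero-mean Gaussian field with autocovariance
    # 2 p (1-p) * mu_el * Omega_TEM*(r), the long-range term the
    # correlated-electron probability imprints on flat-field Pearson
    # coefficients
    amp <- 2 * beam$p * (1 - beam$p) * mean(mu_el)
    s_tem <- beam_sigma_tem(om_tem)
    s <- s_tem / sqrt(2)
    h <- sqrt(amp / (pi * s^2))
    w <- gaussian_kernel(s, radius = min(ceiling(3 * s),
                                         (min(m, n) - 1L) %/% 2L),
                         normalization = "height")
    z <- matrix(stats::rnorm(m * n), m, n)
    e <- pmax(e + h * circ_convolve(z, w$omega), 0)
  }

  base <- det$g * circ_convolve(e, det$psf$omega)

  # Brighter-fatter blur acts on the smoothed signal before the
  # fixed-pattern modulation: the noise model lets beta_BF smooth only the
  # Poisson term while leaving the fixed-pattern term untouched, so the
  # consistent forward model must not smear the gain pattern.
  beta_bf_applied <- 1
  if (!is.null(det$bf_curve)) {
    beta_bf_applied <- det$bf_curve(mean(base))
    sbf <- bf_sigma_forward(beta_bf_applied, det$psf)
    if (sbf > 0) {
      base <- circ_convolve(base, gaussian_kernel(sbf, radius = 3L)$omega)
    }
  }
  sig_c <- base * det$gain_map

  set.seed(derive_seed(seed, 2L))
  therm <- matrix(stats::rpois(m * n, det$dark_rate * t_acq), m, n)
  pre <- sig_c + det$g_c * therm

  if (any(det$nonlin != 0)) {
    q <- quadrant_ranges(det$shape)
    for (nm in names(q)) {
      pre[q[[nm]]$rows, q[[nm]]$cols] <-
        distort_counts(pre[q[[nm]]$rows, q[[nm]]$cols],
                       det$g_c * det$read_offset[nm], det$nonlin)
    }
  }

  ro <- readout_noise(det, derive_seed(seed, 3L))
  out <- pre + ro$noise
  nsat <- sum(out > det$full_well)
  if (nsat > 0) {
    warning(sprintf("%d pixels clamped at the full-well ceiling", nsat))
    out[out > det$full_well] <- det$full_well
  }
  ccd_frame(out, t_acq, "signal", seed,
            truth = list(s_el_mean = mean(mu_el),
                         s_c_mean = det$g * mean(mu_el),
                         raw_mean = mean(out),
                         beta_bf = beta_bf_applied,
                         row_offsets = ro$row_offsets))
}

#' Simulate a dark frame
#'
#' Closed-shutter exposure: Poisson dark counts plus per-quadrant read-out
#' noise, integer row-bias offsets and the read-out offset.
#'
#' @inheritParams simulate_frame
#' @return a `ccd_frame` of kind `"dark"`.
#' @export
simulate_dark <- function(det, t_acq, seed) {
  stopifnot(inherits(det, "detector_model"), t_acq >= 0)
  m <- det$shape[1]; n <- det$shape[2]
  set.seed(derive_seed(seed, 2L))
  therm <- matrix(stats::rpois(m * n, det$dark_rate * t_acq), m, n)
  ro <- readout_noise(det, derive_seed(seed, 3L))
  ccd_frame(det$g_c * therm + ro$noise, t_acq, "dark", seed,
            truth = list(row_offsets = ro$row_offsets))
}

#' Simulate a flat-field acquisition stack
#'
#' The gain-reference acquisition protocol: `n_signal` frames under
#' homogeneous illumination interleaved with `n_dark` dark frames of the
#' same exposure, with independent per-frame seed streams.  Ground truth
#' for recovery tests travels in the `truth` element.
#'
#' @inheritParams simulate_frame
#' @param n_signal,n_dark number of signal and dark frames.
#' @return a list with elements `signal` (list of frames), `dark` (list of
#'   frames) and `truth` (ground-truth parameter record).
#' @export
simulate_flat_stack <- function(det, beam, n_signal = 30L, n_dark = 30L,
                                t_acq = 0.85, seed = 1L) {
  signal <- lapply(seq_len(n_signal), function(k)
    simulate_frame(det, beam, t_acq, derive_seed(seed, 10L, k)))
  dark <- lapply(seq_len(n_dark), function(k)
    simulate_dark(det, t_acq, derive_seed(seed, 20L, k)))
  truth <- list(
    g = det$g, beta_conv = det$beta_conv,
    beta_g = det$g * det$beta_conv,
    read_sigma = det$read_sigma, row_sigma = det$row_sigma,
    dark_rate = mean(det$dark_rate), read_offset = det$read_offset,
    sigma_qe = stats::sd(det$gain_map),
    s_c_mean = if (n_signal > 0) signal[[1]]$truth$s_c_mean else NA_real_,
    row_sd_realized = realized_row_sd(c(signal, dark))
  )
  list(signal = signal, dark = dark, truth = truth)
}

# Pooled SD of the integer row offsets actually drawn for a set of frames.
realized_row_sd <- function(frames) {
  offs <- unlist(lapply(frames, function(f) unlist(f$truth$row_offsets)))
  if (!length(offs)) return(NA_real_)
  sqrt(mean(offs^2))
}

#' Inject cosmic-ray spikes
#'
#' Adds `Poisson(rate * t_acq)` isolated high-amplitude spikes (at least
#' 10 sample SDs above the frame mean) at uniform random positions,
#' emulating the external counting events that accumulate linearly with
#' exposure time.
#'
#' @param frame a `ccd_frame`.
#' @param rate expected events per second.
#' @param seed RNG seed.
#' @return the contaminated frame; attribute `"cosmic_mask"` marks the hit
#'   pixels.
#' @export
inject_cosmic_rays <- function(frame, rate, seed = 1L) {
  stopifnot(inherits(frame, "ccd_frame"), rate >= 0)
  set.seed(seed)
  nev <- stats::rpois(1, rate * frame$t_acq)
  mask <- matrix(FALSE, nrow(frame$data), ncol(frame$data))
  if (nev > 0) {
    idx <- sample.int(length(frame$data), nev, replace = FALSE)
    s <- stats::sd(frame$data)
    amp <- mean(frame$data) + (10 + stats::rexp(nev, 1 / 5)) * s
    frame$data[idx] <- amp
    mask[idx] <- TRUE
  }
  attr(frame, "cosmic_mask") <- mask
  frame
}
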