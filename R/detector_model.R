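# Detector and beam models: the ground-truth parameter sets driving the
# forward simulator.

#' Detector model
#'
#' All simulator parameters of a four-quadrant scintillation-coupled CCD:
#' composite gain `g` (counts per incident beam electron, the product of
#' the unidentifiable fluorescence/fiber/CCD layer gains with the ADC
#' conversion gain `g_c`), detector PSF, unit-mean fixed-pattern gain map,
#' dark-current map, per-quadrant read-out/row/offset noise, a polynomial
#' gain non-linearity, and an optional signal-dependent brighter-fatter
#' curve.  The quadrant layout is 2 x 2 (Q1 top-left, Q2 top-right, Q3
#' bottom-left, Q4 bottom-right), each with its own ADC.
#'
#' Defaults emulate a 2k-class TEM camera at desk scale: smoothed gain
#' `beta * g` of about 1.55 counts/electron with a Gaussian PSF of
#' FWHM 2 pixels, read noise 4 counts, integer row-bias noise of nominal
#' SD 0.6 counts, offset 252 counts, dark current 1.2 counts/s.
#'
#' @param shape detector dimensions `c(rows, cols)`; both even.
#' @param g composite gain in counts per beam electron.  The default picks
#'   `g` so that `g * beta_conv(psf)` is 1.55 counts/electron.
#' @param g_c ADC conversion gain (counts per charge carrier); read, row,
#'   offset and thermal terms are specified in counts at `g_c = 1`.
#' @param psf_fwhm detector PSF full width at half maximum in pixels (used
#'   when `psf` is not given).
#' @param psf a `ccd_kernel` overriding `psf_fwhm`.
#' @param sigma_qe relative SD of the fixed-pattern (quantum-efficiency)
#'   gain map.
#' @param gain_map explicit unit-mean positive gain map (drawn from
#'   `sigma_qe` under `seed` when omitted).
#' @param dark_rate dark current in counts per second per pixel (scalar or
#'   map).
#' @param read_sigma,row_sigma,read_offset per-quadrant read-out noise SD,
#'   row-bias SD and read-out offset (counts); scalars are recycled to the
#'   four quadrants.
#' @param nonlin polynomial non-linearity coefficients `c(x1, x2, x3)` in
#'   the counts domain (forward distortion `S - x1 - x2 S^2 - x3 S^3`).
#' @param bf_curve optional brighter-fatter curve: a [bf_curve_linear()]
#'   object or any function mapping counts to a smoothing factor
#'   `beta_BF <= 1`.
#' @param full_well saturation ceiling in counts.
#' @param seed seed used to draw the gain map (ignored when `gain_map` is
#'   supplied).
#' @return an object of class `detector_model`.
#' @export
detector_model <- function(shape = c(256L, 256L),
                           g = NULL,
                           g_c = 1,
                           psf_fwhm = 2.0,
                           psf = NULL,
                           sigma_qe = 0.067,
                           gain_map = NULL,
                           dark_rate = 1.2,
                           read_sigma = 4.0,
                           row_sigma = 0.6,
                           read_offset = 252,
                           nonlin = c(0, 0, 0),
                           bf_curve = NULL,
                           full_well = 65535,
                           seed = 20260928L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape >= 4), all(shape %% 2L == 0L))
  if (is.null(psf)) psf <- gaussian_kernel(fwhm_to_sigma(psf_fwhm))
  stopifnot(inherits(psf, "ccd_kernel"), psf$normalization == "sum")
  bconv <- sum(psf$omega^2)
  if (is.null(g)) g <- 1.55 / bconv
  stopifnot(g > 0, g_c > 0)
  if (is.null(gain_map)) {
    set.seed(derive_seed(seed, 1L))
    gain_map <- matrix(1 + sigma_qe * stats::rnorm(prod(shape)),
                       shape[1], shape[2])
    gain_map[gain_map < 0.2] <- 0.2
    gain_map <- gain_map / mean(gain_map)
  }
  stopifnot(all(dim(gain_map) == shape), all(gain_map > 0),
            abs(mean(gain_map) - 1) < 1e-6)
  if (length(dark_rate) == 1) {
    dark_rate <- matrix(dark_rate, shape[1], shape[2])
  }
  stopifnot(all(dim(dark_rate) == shape), all(dark_rate >= 0))
  rec4 <- function(x) {
    if (length(x) == 1) x <- rep(x, 4)
    stopifnot(length(x) == 4)
    stats::setNames(as.numeric(x), c("Q1", "Q2", "Q3", "Q4"))
  }
  read_sigma <- rec4(read_sigma); row_sigma <- rec4(row_sigma)
  read_offset <- rec4(read_offset)
  stopifnot(all(read_sigma >= 0), all(row_sigma >= 0))
  stopifnot(is.numeric(nonlin), length(nonlin) == 3)
  structure(list(shape = shape, g = g, g_c = g_c, g_d = g / g_c,
                 psf = psf, beta_conv = bconv,
                 gain_map = gain_map, sigma_qe = sigma_qe,
                 dark_rate = dark_rate,
                 read_sigma = read_sigma, row_sigma = row_sigma,
                 read_offset = read_offset,
                 nonlin = as.numeric(nonlin), bf_curve = bf_curve,
                 full_well = full_well),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model %dx%d>\n", x$shape[1], x$shape[2]))
  cat(sprintf("  gain g = %.4g counts/electron (g_c = %.3g), beta_conv = %.4g\n",
              x$g, x$g_c, x$beta_conv))
  cat(sprintf("  smoothed gain beta_conv*g = %.4g counts/electron\n",
              x$beta_conv * x$g))
  cat(sprintf("  read sigma: %s | row sigma: %s | offset: %s\n",
              paste(signif(x$read_sigma, 3), collapse = "/"),
              paste(signif(x$row_sigma, 3), collapse = "/"),
              paste(signif(x$read_offset, 4), collapse = "/")))
  cat(sprintf("  dark rate %.3g counts/s, sigma_QE = %.3g, nonlin = (%g, %g, %g)\n",
              mean(x$dark_rate), stats::sd(x$gain_map), x$nonlin[1],
              x$nonlin[2], x$nonlin[3]))
  invisible(x)
}

#' Beam model
#'
#' The illumination reaching the detector: expected source electrons per
#' pixel per second, the height-one beam-disc kernel `Omega_TEM*`, and the
#' probability `p` of correlated electrons within the beam.  Correlated
#' electrons share a common origin (Coulomb interactions near the gun) and
#' are laterally displaced together, which imprints a long-range component
#' `2 p (1-p) Omega_TEM*` on the Pearson coefficients of flat frames.
#'
#' @param s_src expected electrons per pixel per second at the source
#'   plane (scalar or matrix over the detector).
#' @param p probability of correlated electrons, in `[0, 1]`.
#' @param omega_tem height-one beam-disc kernel; the default delta kernel
#'   models flat illumination already broader than the detector.
#' @return an object of class `beam_model`.
#' @export
beam_model <- function(s_src, p = 0, omega_tem = NULL) {
  stopifnot(p >= 0, p <= 1, all(s_src >= 0))
  if (is.null(omega_tem)) {
    omega_tem <- ccd_kernel(matrix(1, 1, 1), "height")
  }
  stopifnot(inherits(omega_tem, "ccd_kernel"),
            omega_tem$normalization == "height")
  structure(list(s_src = s_src, p = p, omega_tem = omega_tem),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model s_src ~ %.4g e-/px/s, p = %.3g, disc %dx%d>\n",
              mean(x$s_src), x$p, nrow(x$omega_tem$omega),
              ncol(x$omega_tem$omega)))
  invisible(x)
}

#' Flat illumination targeting a detector intensity
#'
#' Builds a [beam_model()] whose expected detector signal is `s_c` counts
#' per pixel at exposure `t_acq`, accounting for the gain and for the mass
#' of the height-one beam-disc kernel.
#'
#' @param det a [detector_model()].
#' @param s_c target mean intensity (counts/pixel).
#' @param t_acq exposure time (s).
#' @param p correlated-electron probability.
#' @param omega_tem optional height-one beam-disc kernel.
#' @return a `beam_model`.
#' @export
flat_beam <- function(det, s_c, t_acq, p = 0, omega_tem = NULL) {
  a <- if (is.null(omega_tem)) 1 else sum(omega_tem$omega)
  beam_model(s_src = s_c / (det$g * t_acq * a), p = p,
             omega_tem = omega_tem)
}

#' Linear brighter-fatter curve
#'
#' A convenience parameterization of the signal-dependent smoothing factor
#' `beta_BF(S) = 1 - slope * (S - s_ref)`, anchored at 1 at the reference
#' intensity, clipped to `(0, 1.1]`.  Used both as simulator ground truth
#' and as a simple stand-in where a fitted [estimate_bf_curve()] table is
#' not available.
#'
#' @param s_ref reference intensity in counts (where the curve equals 1).
#' @param slope fractional decrease of `beta_BF` per count.
#' @return a function of counts, class `bf_curve_fn`.
#' @export
bf_curve_linear <- function(s_ref, slope = 2e-7) {
  f <- function(s) pmin(pmax(1 - slope * (s - s_ref), 1e-3), 1.1)
  class(f) <- c("bf_curve_fn", class(f))
  attr(f, "s_ref") <- s_ref
  attr(f, "slope") <- slope
  f
}
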