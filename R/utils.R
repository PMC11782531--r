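# Internal helpers: FFT shifts, circular convolution, seed streams, quadrants.

# FFT shifts for centred odd-dimension grids; exact inverses of each other.
# to_origin moves the central element to [1, 1]; to_center undoes it.
to_origin <- function(x) {
  m <- nrow(x); n <- ncol(x)
  x[((seq_len(m) - 1L + (m %/% 2L)) %% m) + 1L,
    ((seq_len(n) - 1L + (n %/% 2L)) %% n) + 1L, drop = FALSE]
}

to_center <- function(x) {
  m <- nrow(x); n <- ncol(x)
  x[((seq_len(m) - 1L - (m %/% 2L)) %% m) + 1L,
    ((seq_len(n) - 1L - (n %/% 2L)) %% n) + 1L, drop = FALSE]
}

# Embed a centred (odd-dimension) kernel into an M x N wrap-around array with
# the kernel origin at element [1, 1], as required for FFT-based circular
# convolution.
embed_kernel <- function(omega, m, n) {
  km <- matrix(0, m, n)
  rr <- (nrow(omega) - 1L) %/% 2L
  rc <- (ncol(omega) - 1L) %/% 2L
  if (2L * rr + 1L > m || 2L * rc + 1L > n)
    stop("kernel larger than target grid")
  for (i in seq_len(nrow(omega))) {
    ti <- ((i - rr - 1L) %% m) + 1L
    for (j in seq_len(ncol(omega))) {
      tj <- ((j - rc - 1L) %% n) + 1L
      km[ti, tj] <- km[ti, tj] + omega[i, j]
    }
  }
  km
}

#' Circular convolution with a centred kernel
#'
#' FFT-based periodic convolution, the convolution convention used
#' throughout the package (it matches the periodogram autocovariance
#' estimator).  The kernel must have odd dimensions and fit inside the
#' image.
#'
#' @param img numeric matrix.
#' @param omega centred kernel matrix (or the `omega` of a [ccd_kernel()]).
#' @return the convolved matrix.
#' @export
circ_convolve <- function(img, omega) {
  km <- embed_kernel(omega, nrow(img), ncol(img))
  Re(stats::fft(stats::fft(img) * stats::fft(km), inverse = TRUE)) / length(img)
}

#' Deterministic seed streams
#'
#' Expands one master seed into reproducible per-frame / per-stage seed
#' streams (plain integer hashing, kept below 2^31), so any single
#' simulated frame can be regenerated in isolation.
#'
#' @param master master seed.
#' @param ... integer stream indices.
#' @return an integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

#' Quadrant layout helpers
#'
#' The 2 x 2 quadrant layout (Q1 top-left, Q2 top-right, Q3 bottom-left,
#' Q4 bottom-right; each quadrant has its own ADC and noise parameters),
#' and per-quadrant means/sample variances of a frame matrix.
#'
#' @param shape frame dimensions `c(rows, cols)`.
#' @return `quadrant_ranges()`: a named list of row/column index ranges.
#' @export
quadrant_ranges <- function(shape) {
  m <- shape[1]; n <- shape[2]
  hm <- m %/% 2L; hn <- n %/% 2L
  list(
    Q1 = list(rows = seq_len(hm),        cols = seq_len(hn)),
    Q2 = list(rows = seq_len(hm),        cols = seq(hn + 1L, n)),
    Q3 = list(rows = seq(hm + 1L, m),    cols = seq_len(hn)),
    Q4 = list(rows = seq(hm + 1L, m),    cols = seq(hn + 1L, n))
  )
}

clip_negative <- function(x) {
  x[x < 0] <- 0
  x
}

#' Gaussian width conversions
#'
#' Convert between the standard deviation and the full width at half maximum
#' of a Gaussian profile, `FWHM = 2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param sigma standard deviation (pixels).
#' @param fwhm full width at half maximum (pixels).
#' @return the converted width.
#' @export
gaussian_fwhm <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' @rdname gaussian_fwhm
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
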