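# Post-binning of frames, propagation of all noise terms under binning,
# and the EELS spectrum noise model.

block_sum <- function(x, V, H, from_back = FALSE) {
  nr <- (nrow(x) %/% V) * V
  nc <- (ncol(x) %/% H) * H
  if (nr == 0 || nc == 0) stop("binning values exceed the frame")
  if (from_back) {
    x <- x[seq(nrow(x) - nr + 1L, nrow(x)), seq(ncol(x) - nc + 1L, ncol(x)),
           drop = FALSE]
  } else {
    x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  }
  # sum V rows, then H columns
  g1 <- rowsum(x, rep(seq_len(nr %/% V), each = V))
  out <- t(rowsum(t(g1), rep(seq_len(nc %/% H), each = H)))
  dimnames(out) <- NULL
  out
}

#' Post-bin a frame into H x V blocks
#'
#' Non-overlapping block sums of `H` columns by `V` rows.  Binning values
#' with a prime factor not dividing the frame leave leftover pixels, which
#' are discarded at the edge opposite the anchor; `anchor = "average-both"`
#' returns both crops so downstream statistics can be averaged over them.
#'
#' @param frame a `ccd_frame` (or matrix).
#' @param H,V horizontal (columns) and vertical (rows) binning values.
#' @param anchor `"front"`, `"back"`, or `"average-both"`.
#' @return a binned `ccd_frame`, or for `"average-both"` a list with
#'   elements `front` and `back`.
#' @export
post_bin <- function(frame, H = 1L, V = 1L,
                     anchor = c("front", "back", "average-both")) {
  anchor <- match.arg(anchor)
  isf <- inherits(frame, "ccd_frame")
  x <- if (isf) frame$data else frame
  stopifnot(H >= 1, V >= 1, H <= ncol(x), V <= nrow(x))
  wrap <- function(b) {
    if (!isf) return(b)
    out <- frame; out$data <- b; out$kind <- paste0(frame$kind, "_binned")
    out
  }
  if (anchor == "average-both") {
    return(list(front = wrap(block_sum(x, V, H, FALSE)),
                back = wrap(block_sum(x, V, H, TRUE))))
  }
  wrap(block_sum(x, V, H, anchor == "back"))
}

#' Signal distribution factor alpha
#'
#' How unevenly the expected signal is spread over the pixels entering one
#' binned value: `alpha = sum (S_ij / sum S)^2` over the bin, which is
#' `1/(H V)` for a flat signal and 1 when all signal sits in one pixel.
#' The `normalized` variant rescales by the bin size
#' (`H V * sum (S/sumS)^2`, equal to 1 for flat signal); the noise-model
#' closures in [predict_binned_variance()] and [eels_variance_model()] use
#' the normalized form together with the binned reference uncertainty,
#' which already carries the `1/(H V)` scaling.
#'
#' @param s_grid expected counts over one bin (vector or matrix).
#' @param normalized rescale by the number of pixels in the bin.
#' @return the dimensionless distribution factor.
#' @export
alpha_factor <- function(s_grid, normalized = FALSE) {
  s <- as.vector(s_grid)
  tot <- sum(s)
  if (tot <= 0) stop("bin carries no signal")
  a <- sum((s / tot)^2)
  if (normalized) a * length(s) else a
}

#' Binned gain-reference uncertainty
#'
#' Propagates the reference uncertainty to `H x V` binned pixels: the
#' Poisson part scales with the binned coefficient sum of the reference
#' Pearson field (`beta_{H,V} = beta_1 * rho00*_{H,V} / (H V)`), the
#' detector-noise part adds linearly over the bin,
#' `k^2 = (w beta*g S rho00* + 2 w H V glin^2 sigma_d^2) / (w H V S)^2`.
#' Reduces to the unbinned theoretical value at `H = V = 1`.
#'
#' @param s_ref_c per-frame reference intensity (counts per unbinned
#'   pixel).
#' @param w number of summed pairs.
#' @param beta_g unbinned smoothed gain (counts/electron).
#' @param sigma_d2 per-frame detector-noise variance (counts^2).
#' @param rho_ref the reference `ccd_pearson` field.
#' @param H,V binning values.
#' @param g_lin_mean mean linearization factor (1 for a linear detector).
#' @param within_frame additionally apply the finite-frame correlation
#'   factor of the binned field (for within-frame sample variances).
#' @return the binned `k_ref`.
#' @export
binned_kref <- function(s_ref_c, w, beta_g, sigma_d2, rho_ref,
                        H = 1L, V = 1L, g_lin_mean = 1,
                        within_frame = FALSE) {
  stopifnot(inherits(rho_ref, "ccd_pearson"))
  bp <- bin_pearson(rho_ref, H = H, V = V)
  r0 <- bp$rho00_star
  if (within_frame) r0 <- r0 * beta_corr(bp$rho_bin)
  k2 <- (w * beta_g * s_ref_c * r0 + 2 * w * H * V * g_lin_mean^2 * sigma_d2) /
    (w * H * V * s_ref_c)^2
  sqrt(k2)
}

#' Predicted variance of post-binned corrected images
#'
#' The full noise model under binning, per binned pixel: the smoothed
#' Poisson term `beta*g_{H,V} beta_BF sum(S)` (with its reference-noise
#' modulation `k^2`), the fixed-pattern term `alpha k^2 (sum S)^2`, and
#' the detector noise, where the isotropic read/thermal part adds over the
#' `H V` pixels while the row-noise part is constant along rows and
#' therefore adds quadratically in `H`.
#'
#' @param s_grid expected counts per unbinned pixel (matrix, already
#'   cropped to a multiple of the binning values).
#' @param H,V binning values.
#' @param k_binned binned reference/linearization uncertainty (from
#'   [binned_kref()], plus any `k_lin` in quadrature).
#' @param beta_g_binned binned smoothed gain `g * beta_{H,V}`
#'   (counts/electron).
#' @param beta_bf_binned binned brighter-fatter factor.
#' @param sigma_d_corr2 per-pixel corrected detector-noise variances,
#'   a named vector `c(pix = read+thermal, row = row)` (counts^2).
#' @param alpha distribution factor per bin (normalized convention);
#'   computed from `s_grid` when `NULL`.
#' @return matrix of predicted variances per binned pixel (counts^2).
#' @export
predict_binned_variance <- function(s_grid, H = 1L, V = 1L, k_binned,
                                    beta_g_binned, beta_bf_binned = 1,
                                    sigma_d_corr2 = c(pix = 0, row = 0),
                                    alpha = NULL) {
  stopifnot(is.matrix(s_grid), nrow(s_grid) %% V == 0,
            ncol(s_grid) %% H == 0)
  ssum <- block_sum(s_grid, V, H)
  if (is.null(alpha)) {
    s2sum <- block_sum(s_grid^2, V, H)
    alpha <- H * V * s2sum / ssum^2
  }
  pix <- if ("pix" %in% names(sigma_d_corr2)) sigma_d_corr2[["pix"]] else
    sigma_d_corr2[[1]]
  row <- if ("row" %in% names(sigma_d_corr2)) sigma_d_corr2[["row"]] else 0
  det2 <- 2 * (H * V * pix + H^2 * V * row)
  (1 + k_binned^2) * beta_g_binned * beta_bf_binned * ssum +
    alpha * k_binned^2 * ssum^2 + det2
}

#' EELS noise model
#'
#' Container for the spectrum-domain noise parameters after vertically
#' summing `V` detector rows per channel: the gain `g`, the summed-system
#' smoothing `beta_eels` (`beta_{EELS,1,V}`), the binned reference
#' uncertainty, the per-side detector-noise sums (the EELS band spans two
#' quadrants per channel, whose noises add), and optionally the beam
#' correlation probability and composed ZLP kernel.
#'
#' @param V rows summed per channel.
#' @param g composite gain (counts/electron).
#' @param beta_eels smoothing factor of the summed system.
#' @param kref_binned binned reference uncertainty `k_{ref,1,V}`.
#' @param sigma_d_sets detector-noise variance per channel summed over the
#'   V rows, named `c(left = , right = )` (counts^2), reflecting the
#'   quadrant pairs each side of the detector crosses.
#' @param p_stem correlated-electron probability in STEM mode.
#' @param zlp_kernel optional `ccd_kernel` (height-one) of the 2D ZLP.
#' @return an object of class `eels_model`.
#' @export
eels_model <- function(V = 260L, g, beta_eels, kref_binned,
                       sigma_d_sets, p_stem = 0, zlp_kernel = NULL) {
  stopifnot(V >= 1, g > 0, beta_eels > 0, kref_binned >= 0,
            p_stem >= 0, p_stem <= 1)
  structure(list(V = as.integer(V), g = g, beta_eels = beta_eels,
                 kref_binned = kref_binned, sigma_d_sets = sigma_d_sets,
                 p_stem = p_stem, zlp_kernel = zlp_kernel),
            class = "eels_model")
}

#' Per-channel noise variance of an EEL spectrum
#'
#' Applies the binning noise model to the vertical summation that turns
#' the 2D EELS region into a spectrum: per channel `i`,
#' `g beta_EELS (1 + k^2) sum_j S + alpha_i k^2 (sum_j S)^2 +
#' 2 sum_j sigma_d_corr^2`, with the distribution factor computed from the
#' vertical signal profile of each channel (a concentrated ZLP row profile
#' raises it far above the flat-illumination value).
#'
#' @param spectrum_2d expected counts on the 2D EELS region (rows x
#'   channels), `nrow >= model$V` (the first `V` rows are used).
#' @param model an [eels_model()].
#' @return list with `spectrum` (summed counts per channel) and `variance`
#'   (counts^2 per channel).
#' @export
eels_variance_model <- function(spectrum_2d, model) {
  stopifnot(inherits(model, "eels_model"), is.matrix(spectrum_2d),
            nrow(spectrum_2d) >= model$V)
  s <- spectrum_2d[seq_len(model$V), , drop = FALSE]
  ssum <- colSums(s)
  nchan <- ncol(s)
  alpha <- vapply(seq_len(nchan), function(i)
    alpha_factor(s[, i], normalized = TRUE), numeric(1))
  side <- rep(model$sigma_d_sets[["left"]], nchan)
  if (nchan > 1) {
    side[seq(nchan %/% 2 + 1L, nchan)] <- model$sigma_d_sets[["right"]]
  }
  bg <- model$g * model$beta_eels
  k2 <- model$kref_binned^2
  v <- bg * (1 + k2) * ssum + alpha * k2 * ssum^2 + 2 * side
  list(spectrum = ssum, variance = v)
}

#' Compose the 2D zero-loss-peak kernel
#'
#' `Omega_ZLP* = Omega_d (x) Omega_disp (x) Omega_STEM*`, the measurable 2D
#' representation of the ZLP combining detector PSF, spectrometer
#' dispersion and the STEM probe on the entrance aperture, height-one
#' normalized.  Asymmetric dispersion kernels are preserved (convolution,
#' no symmetrization).
#'
#' @param omega_d,omega_disp,omega_stem `ccd_kernel`s on compatible grids.
#' @return a height-one `ccd_kernel`.
#' @export
compose_zlp <- function(omega_d, omega_disp, omega_stem) {
  ks <- list(omega_d, omega_disp, omega_stem)
  stopifnot(all(vapply(ks, inherits, logical(1), "ccd_kernel")))
  rv <- sum(vapply(ks, function(k) (nrow(k$omega) - 1L) %/% 2L, integer(1)))
  rh <- sum(vapply(ks, function(k) (ncol(k$omega) - 1L) %/% 2L, integer(1)))
  rv <- max(rv, 1L); rh <- max(rh, 1L)
  grid <- matrix(0, 2L * rv + 1L, 2L * rh + 1L)
  grid[rv + 1L, rh + 1L] <- 1
  for (k in ks) grid <- circ_convolve(grid, k$omega)
  grid[grid < 0] <- 0
  ccd_kernel(grid, "height")
}
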