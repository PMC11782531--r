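# Measurement pipeline: artifact removal, dark subtraction, row/read/thermal
# decomposition, gain-reference construction and application, and the k_ref
# and smoothed-gain estimators.

#' Remove cosmic-ray spikes from a frame
#'
#' Pixels beyond `nsigma` sample SDs from the frame mean (both sides, since
#' subtracted darks can carry negative spikes) are flagged; the statistics
#' are recomputed once without the flagged pixels (two-pass) and the flags
#' refreshed.  Flagged pixels and their 3 x 3 neighbourhood are replaced by
#' the robust frame mean.
#'
#' @param frame a `ccd_frame`.
#' @param nsigma clipping distance in sample SDs (default 5).
#' @param max_frac maximum tolerated fraction of flagged pixels; more is
#'   treated as contamination and raises an error.
#' @return a list with `frame` (cleaned) and `mask` (logical matrix of
#'   flagged pixels, before neighbourhood dilation).
#' @export
remove_cosmic_rays <- function(frame, nsigma = 5, max_frac = 0.01) {
  stopifnot(inherits(frame, "ccd_frame"))
  x <- frame$data
  mu <- mean(x); s <- stats::sd(x)
  flag <- abs(x - mu) > nsigma * s
  if (any(flag)) {
    mu <- mean(x[!flag]); s <- stats::sd(x[!flag])
    flag <- abs(x - mu) > nsigma * s
  }
  frac <- mean(flag)
  if (frac > max_frac) {
    stop(sprintf("%.2f%% of pixels flagged as spikes (> %.2f%%): frame too contaminated",
                 100 * frac, 100 * max_frac))
  }
  if (any(flag)) {
    idx <- which(flag, arr.ind = TRUE)
    m <- nrow(x); n <- ncol(x)
    for (k in seq_len(nrow(idx))) {
      rr <- pmax(1L, idx[k, 1] - 1L):pmin(m, idx[k, 1] + 1L)
      cc <- pmax(1L, idx[k, 2] - 1L):pmin(n, idx[k, 2] + 1L)
      x[rr, cc] <- mu
    }
  }
  frame$data <- x
  list(frame = frame, mask = flag)
}

#' Dark-frame subtraction
#'
#' Pixel-wise subtraction of a matched dark frame removes the read-out
#' offset, dark-current structure and bias pattern; the price is a doubling
#' of the detector-noise variance, as two frames are subtracted.
#'
#' @param signal,dark `ccd_frame`s of matching shape and exposure time.
#' @return a `ccd_frame` of kind `"dark_subtracted"`.
#' @export
dark_subtract <- function(signal, dark) {
  stopifnot(inherits(signal, "ccd_frame"), inherits(dark, "ccd_frame"))
  if (!all(dim(signal$data) == dim(dark$data)))
    stop("frame shapes do not match")
  if (abs(signal$t_acq - dark$t_acq) > 1e-9)
    stop("exposure times do not match")
  out <- signal
  out$data <- signal$data - dark$data
  out$kind <- "dark_subtracted"
  out$truth <- signal$truth
  out
}

#' Split a dark-subtracted frame into row offsets and residual noise
#'
#' Row-bias fluctuations between read-outs are integer-valued steps; per
#' quadrant, each row's mean is rounded to the nearest integer (ties away
#' from zero) and subtracted.  The decomposition is exact: the input equals
#' residual + offsets.  The residual carries read-out plus thermal noise,
#' the offsets frame the row noise.
#'
#' @param frame a dark-subtracted `ccd_frame`.
#' @return a list with `residual` and `offsets` (both `ccd_frame`s) and
#'   `row_offsets` (per-quadrant integer vectors).
#' @export
split_row_noise <- function(frame) {
  stopifnot(inherits(frame, "ccd_frame"))
  x <- frame$data
  off <- matrix(0, nrow(x), ncol(x))
  q <- quadrant_ranges(dim(x))
  row_offsets <- list()
  for (nm in names(q)) {
    rows <- q[[nm]]$rows; cols <- q[[nm]]$cols
    rm_ <- rowMeans(x[rows, cols, drop = FALSE])
    ro <- sign(rm_) * floor(abs(rm_) + 0.5)   # round half away from zero
    off[rows, cols] <- ro
    row_offsets[[nm]] <- ro
  }
  res <- frame; res$data <- x - off; res$kind <- "row_free"
  offf <- frame; offf$data <- off; offf$kind <- "row_offsets"
  list(residual = res, offsets = offf, row_offsets = row_offsets)
}

#' @rdname quadrant_ranges
#' @param x numeric matrix.
#' @export
quadrant_var <- function(x) {
  q <- quadrant_ranges(dim(x))
  vapply(q, function(z) stats::var(as.vector(x[z$rows, z$cols])), numeric(1))
}

#' @rdname quadrant_ranges
#' @export
quadrant_mean <- function(x) {
  q <- quadrant_ranges(dim(x))
  vapply(q, function(z) mean(x[z$rows, z$cols]), numeric(1))
}

#' Detector-noise scale factor of gain normalization
#'
#' The per-quadrant factor `phi^-2 + sigma_ref^2 / phi^4` by which
#' applying a gain reference rescales the detector-noise variance.
#'
#' @param ref a `gain_reference`.
#' @return named per-quadrant factors.
#' @export
gain_ref_noise_scale <- function(ref) {
  ref$phi^-2 + ref$sigma_ref^2 / ref$phi^4
}

#' Read-out / thermal noise decomposition by exposure-time regression
#'
#' Thermal noise accumulates with exposure while read-out noise does not:
#' ordinary least squares of the single-frame variance of dark-subtracted
#' frame pairs against exposure time separates the two, per quadrant.  Row
#' noise is removed first by exact per-quadrant row-mean subtraction, and
#' its variance estimated from the raw row means with the read/thermal
#' contribution subtracted (unbiased at any quadrant width, unlike the
#' integer-rounding decomposition of [split_row_noise()], which needs wide
#' rows).  For frames with a gain reference applied,
#' both regression parameters scale by the reference factor
#' `phi^-2 + sigma_ref^2/phi^4`, which is divided out again so the budget
#' reports detector-domain variances.
#'
#' @param frames list of dark-subtracted `ccd_frame`s (pairs of darks) with
#'   at least 3 distinct exposure times; cosmic rays removed.
#' @param ref the `gain_reference` applied to the frames, or `NULL` for
#'   unprocessed frames.
#' @return an object of class `noise_budget`: per-quadrant `read_var`
#'   (counts^2), `dark_rate_var` (counts^2 per second), `row_var`
#'   (counts^2), 95% confidence intervals, and the scale factors used.
#' @export
regress_read_thermal <- function(frames, ref = NULL) {
  stopifnot(is.list(frames), length(frames) >= 3)
  tt <- vapply(frames, function(f) f$t_acq, numeric(1))
  if (length(unique(tt)) < 3)
    stop("need at least 3 distinct exposure times")
  scale <- if (is.null(ref)) rep(1, 4) else gain_ref_noise_scale(ref)
  names(scale) <- c("Q1", "Q2", "Q3", "Q4")
  vres <- matrix(NA_real_, length(frames), 4,
                 dimnames = list(NULL, names(scale)))
  vrow <- vres
  q <- quadrant_ranges(dim(frames[[1]]$data))
  for (i in seq_along(frames)) {
    for (k in seq_along(q)) {
      sub <- frames[[i]]$data[q[[k]]$rows, q[[k]]$cols, drop = FALSE]
      nc <- ncol(sub)
      rm_ <- rowMeans(sub)
      # exact row-mean removal: unbiased at any quadrant width (the
      # integer-rounding split of split_row_noise needs wide rows to be
      # reliable and is kept as a decomposition, not as this estimator)
      pixvar <- stats::var(as.vector(sub - rm_)) * nc / (nc - 1)
      vres[i, k] <- pixvar
      vrow[i, k] <- mean(rm_^2) - pixvar / nc
    }
  }
  read_var <- dark_rate_var <- row_var <- numeric(4)
  read_ci <- dark_ci <- matrix(NA_real_, 4, 2)
  names(read_var) <- names(dark_rate_var) <- names(row_var) <- names(scale)
  for (k in 1:4) {
    fit <- stats::lm(vres[, k] ~ tt)
    cf <- stats::coef(fit)
    ci <- suppressWarnings(stats::confint(fit, level = 0.95))
    read_var[k] <- cf[1] / 2 / scale[k]
    dark_rate_var[k] <- cf[2] / 2 / scale[k]
    read_ci[k, ] <- ci[1, ] / 2 / scale[k]
    dark_ci[k, ] <- ci[2, ] / 2 / scale[k]
    row_var[k] <- mean(vrow[, k]) / 2 / scale[k]
  }
  neg <- dark_rate_var < 0 | read_var < 0
  if (any(neg)) {
    warning("negative fitted variance clamped at 0 for quadrant(s): ",
            paste(names(scale)[neg], collapse = ", "))
    read_var <- pmax(read_var, 0); dark_rate_var <- pmax(dark_rate_var, 0)
  }
  structure(list(read_var = read_var, dark_rate_var = dark_rate_var,
                 row_var = row_var, read_ci = read_ci, dark_ci = dark_ci,
                 scale = scale, n_frames = length(frames),
                 exposures = sort(unique(tt))),
            class = "noise_budget")
}

#' @export
print.noise_budget <- function(x, ...) {
  cat("<noise_budget> per-quadrant detector noise (counts^2):\n")
  print(round(rbind(read_var = x$read_var,
                    dark_rate_var = x$dark_rate_var,
                    row_var = x$row_var), 4))
  invisible(x)
}

#' Combined detector-noise variance
#'
#' `sigma_d^2 = sigma_read^2 + sigma_row^2 + sigma_therm^2` per quadrant at
#' a given exposure time.
#'
#' @param budget a `noise_budget`.
#' @param t_acq exposure time (s).
#' @return named per-quadrant variances (counts^2).
#' @export
sigma_d2 <- function(budget, t_acq) {
  stopifnot(inherits(budget, "noise_budget"))
  budget$read_var + budget$row_var + budget$dark_rate_var * t_acq
}

#' Build a gain reference from a flat-field stack
#'
#' Sums `w` matched signal/dark pairs acquired under homogeneous
#' illumination, after cosmic-ray removal, and normalizes the summed
#' difference to unit mean over the full detector.  Records the per-frame
#' target intensity, per-quadrant means `phi`, the overall spread
#' `sigma_ref`, and (by default) the measurement uncertainty `k_ref` with
#' its Pearson field, estimated from the same frames via
#' [estimate_kref_autocov()].
#'
#' @param signal_frames,dark_frames matched lists of raw `ccd_frame`s.
#' @param clean remove cosmic rays from every contributing frame first.
#' @param estimate_uncertainty also estimate `k_ref` and the reference
#'   Pearson field from difference-frame autocovariances.
#' @return an object of class `gain_reference`.
#' @export
build_gain_reference <- function(signal_frames, dark_frames, clean = TRUE,
                                 estimate_uncertainty = TRUE) {
  stopifnot(length(signal_frames) >= 1,
            length(signal_frames) == length(dark_frames))
  w <- length(signal_frames)
  if (clean) {
    signal_frames <- lapply(signal_frames,
                            function(f) remove_cosmic_rays(f)$frame)
    dark_frames <- lapply(dark_frames,
                          function(f) remove_cosmic_rays(f)$frame)
  }
  diffs <- Map(dark_subtract, signal_frames, dark_frames)
  ssum <- Reduce(`+`, lapply(diffs, function(f) f$data))
  qm <- quadrant_mean(ssum)
  if (max(qm) / min(qm) > 1.1)
    warning("non-flat illumination: quadrant means differ by more than 10%")
  mu <- mean(ssum)
  if (mu <= 0) stop("summed flat signal must be positive")
  map <- ssum / mu
  if (any(map <= 0))
    stop("gain reference map has non-positive entries; illumination too weak")
  ref <- structure(list(map = map, recip = 1 / map, w = w,
                        s_ref_c = mu / w,
                        phi = quadrant_mean(map),
                        sigma_ref = stats::sd(map),
                        k_ref = NA_real_, rho_ref = NULL,
                        sigma_qe = NA_real_),
                   class = "gain_reference")
  if (estimate_uncertainty) {
    kr <- estimate_kref_autocov(diffs, dark_frames,
                                sigma_ref_all = ref$sigma_ref)
    ref$k_ref <- kr$k_ref
    ref$rho_ref <- kr$rho
    ref$sigma_qe <- sqrt(max(ref$sigma_ref^2 - kr$k_ref^2, 0))
  }
  ref
}

#' @export
print.gain_reference <- function(x, ...) {
  cat(sprintf("<gain_reference %dx%d, w = %d, S_ref = %.4g counts>\n",
              nrow(x$map), ncol(x$map), x$w, x$s_ref_c))
  cat(sprintf("  sigma_ref = %.4g, k_ref = %.4g, phi = %s\n",
              x$sigma_ref, x$k_ref,
              paste(signif(x$phi, 4), collapse = "/")))
  invisible(x)
}

#' Apply a gain reference to a dark-subtracted frame
#'
#' Pixel-wise multiplication by the stored reciprocal map (faster than
#' division) removes the fixed-pattern gain variation, at the cost of
#' imprinting the reference's measurement noise `k_ref` and scaling the
#' detector noise by `phi^-2 + sigma_ref^2/phi^4` per quadrant.
#'
#' @param frame a dark-subtracted `ccd_frame`.
#' @param ref a `gain_reference` of matching shape.
#' @return a `ccd_frame` of kind `"gain_normalized"`.
#' @export
apply_gain_reference <- function(frame, ref) {
  stopifnot(inherits(frame, "ccd_frame"), inherits(ref, "gain_reference"))
  if (!all(dim(frame$data) == dim(ref$map)))
    stop("frame and reference shapes do not match")
  out <- frame
  out$data <- frame$data * ref$recip
  out$kind <- "gain_normalized"
  out
}

#' Theoretical gain-reference uncertainty
#'
#' The closed form for the relative uncertainty of a gain reference built
#' from `w` summed flat/dark pairs at per-frame intensity `s_ref_c` counts:
#' `k^2 = (w * beta*g * s_ref_c + 2 w sigma_d^2) / (w * s_ref_c)^2`.  The
#' first term is the smoothed Poisson noise of the reference signal, the
#' second the (doubled, from dark subtraction) detector noise.
#'
#' @param s_ref_c per-frame reference intensity (counts).
#' @param g composite gain (counts/electron).
#' @param beta total smoothing factor (so `beta * g` is the smoothed gain).
#' @param sigma_d2 detector-noise variance per frame (counts^2).
#' @param w number of summed pairs.
#' @return the predicted `k_ref`.
#' @export
kref_theoretical <- function(s_ref_c, g, beta, sigma_d2, w = 1) {
  stopifnot(s_ref_c > 0, g > 0, beta > 0, sigma_d2 >= 0, w >= 1)
  k2 <- (w * beta * g * s_ref_c + 2 * w * sigma_d2) / (w * s_ref_c)^2
  sqrt(k2)
}

#' Smoothed gain from a measured k_ref
#'
#' Inverts the theoretical `k_ref` relation: knowing the detector noise,
#' `beta*g = s_ref_c * (k^2 - 2 * sum(sigma_d^2) / sum(s_ref_c))`.
#'
#' @param s_ref_c per-frame reference intensity (counts).
#' @param k_ref measured reference uncertainty for `w` summed pairs.
#' @param sigma_d2 per-frame detector-noise variance (counts^2).
#' @param w number of summed pairs.
#' @return the smoothed gain `beta * g` (counts/electron).
#' @export
smoothed_gain_from_kref <- function(s_ref_c, k_ref, sigma_d2, w = 1) {
  w * s_ref_c * (k_ref^2 - 2 * (w * sigma_d2) / (w * s_ref_c)^2)
}

#' k_ref from the difference of two gain references
#'
#' Two references acquired at the same target intensity and `w` differ only
#' by their measurement noise: `k_ref = SD(mapA - mapB) /
#' sqrt(2 (1 + sigma_ref_all^2))`, with the unit-mean convention
#' (`phi = 1`).  The `sqrt(2)` accounts for both references carrying noise,
#' the second factor for the quantum-efficiency modulation of the noise.
#'
#' @param refA,refB `gain_reference`s from the same intensity and `w`.
#' @return the estimated `k_ref`.
#' @export
estimate_kref_difference <- function(refA, refB) {
  stopifnot(inherits(refA, "gain_reference"), inherits(refB, "gain_reference"))
  if (refA$w != refB$w)
    stop("references built from different numbers of frames")
  if (abs(refA$s_ref_c - refB$s_ref_c) > 0.05 * refA$s_ref_c)
    stop("references built at different target intensities")
  s2 <- mean(c(refA$sigma_ref, refB$sigma_ref))^2
  stats::sd(refA$map - refB$map) / sqrt(2 * (1 + s2))
}

#' k_ref and reference Pearson field from difference-frame autocovariances
#'
#' Pairs of pure-signal frames are differenced (cancelling the fixed
#' pattern), their autocovariance fields clipped of negative entries (the
#' circular estimator's zero-sum constraint leaks small negatives into the
#' tails) and corrected by the unclipped autocovariance of dark-frame
#' differences; the quantum-efficiency modulation is divided out with
#' `1 + sigma_ref_all^2`.  Summed over all pairs and normalized by the
#' squared total reference intensity this rebuilds the Poisson part of the
#' theoretical `k_ref` and yields its Pearson field.
#'
#' @param signal_frames list of dark-subtracted pure-signal `ccd_frame`s
#'   (at least 2).
#' @param dark_frames list of raw dark `ccd_frame`s (at least 2).
#' @param sigma_ref_all overall SD of the gain-reference map.
#' @return list with `k_ref` and `rho` (a `ccd_pearson` field).
#' @export
estimate_kref_autocov <- function(signal_frames, dark_frames,
                                  sigma_ref_all) {
  stopifnot(length(signal_frames) >= 2, length(dark_frames) >= 2)
  np <- length(signal_frames) %/% 2L
  npd <- length(dark_frames) %/% 2L
  acc <- NULL
  s_tot <- sum(vapply(signal_frames, function(f) mean(f$data), numeric(1)))
  for (j in seq_len(np)) {
    ds <- signal_frames[[2L * j - 1L]]$data - signal_frames[[2L * j]]$data
    jd <- ((j - 1L) %% npd) + 1L
    db <- dark_frames[[2L * jd - 1L]]$data - dark_frames[[2L * jd]]$data
    ks <- clip_negative(autocovariance_wk(ds)$field)
    kb <- autocovariance_wk(db)$field
    acc <- if (is.null(acc)) ks - kb else acc + (ks - kb)
  }
  acc <- acc / ((1 + sigma_ref_all^2) * s_tot^2)
  ctr <- (dim(acc) + 1L) %/% 2L
  k2 <- acc[ctr[1], ctr[2]]
  if (k2 <= 0) stop("non-positive central element: cannot estimate k_ref")
  shape <- dim(signal_frames[[1]]$data)
  list(k_ref = sqrt(k2),
       rho = pearson_field(acc / k2, shape))
}

#' Smoothed gain and signal Pearson field from flat frames
#'
#' Rebuilds the signal autocovariance from gain-normalized flat frames:
#' `K(signal) = (K+(flat - S_c) - S_c^2 K+(ref) - K(dark diff)) /
#' (1 + k_ref^2)`, where `K+(ref)` is the reference's measured
#' `k_ref^2 * rho` field (removing the imprinted reference noise), the
#' dark-difference field removes the doubled detector noise, and the final
#' division removes the reference's modulation of the Poisson noise.  The
#' smoothed gain `beta*g` is the central element divided by the mean
#' intensity, after correcting the single-frame sample variance for the
#' finite-frame correlation factor of the estimated field.
#'
#' @param flats one or a list of dark-subtracted flat `ccd_frame`s; raw
#'   dark-subtracted frames are gain-normalized with `ref` first.
#' @param ref a `gain_reference` with estimated uncertainty (`k_ref`,
#'   `rho_ref`).
#' @param dark_diffs one or a list of dark-difference `ccd_frame`s
#'   (dark minus dark, matching exposure).
#' @return list with `beta_g` (counts/electron), `rho` (a `ccd_pearson`
#'   field of the signal), `K` (the signal `ccd_acov` field) and `s_c`
#'   (mean intensity in counts).
#' @export
estimate_smoothed_gain <- function(flats, ref, dark_diffs) {
  stopifnot(inherits(ref, "gain_reference"))
  if (is.na(ref$k_ref) || is.null(ref$rho_ref))
    stop("gain reference lacks an uncertainty estimate (k_ref / rho_ref)")
  if (inherits(flats, "ccd_frame")) flats <- list(flats)
  if (inherits(dark_diffs, "ccd_frame")) dark_diffs <- list(dark_diffs)
  flats <- lapply(flats, function(f) {
    if (f$kind != "gain_normalized") apply_gain_reference(f, ref) else f
  })
  dark_diffs <- lapply(dark_diffs, function(f) {
    if (f$kind != "gain_normalized") apply_gain_reference(f, ref) else f
  })
  kstar <- Reduce(`+`, lapply(flats, function(f) autocovariance_wk(f)$field)) /
    length(flats)
  kdb <- Reduce(`+`, lapply(dark_diffs,
                            function(f) autocovariance_wk(f)$field)) /
    length(dark_diffs)
  s_c <- mean(vapply(flats, function(f) mean(f$data), numeric(1)))
  rho_ref <- resize_centred(ref$rho_ref$field,
                            (nrow(kstar) - 1L) %/% 2L,
                            (ncol(kstar) - 1L) %/% 2L)
  ksig <- (clip_negative(kstar) - s_c^2 * ref$k_ref^2 *
             clip_negative(rho_ref) - kdb) / (1 + ref$k_ref^2)
  ctr <- (dim(ksig) + 1L) %/% 2L
  k0 <- ksig[ctr[1], ctr[2]]
  if (k0 <= 0) stop("non-positive central element in the signal autocovariance")
  shape <- dim(flats[[1]]$data)
  rho <- pearson_field(ksig / k0, shape)
  bc <- beta_corr(rho)
  list(beta_g = k0 / (s_c * bc), rho = rho,
       K = acov_field(ksig, shape), s_c = s_c)
}
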