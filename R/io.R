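# Frame-stack I/O: multi-page 32-bit-float TIFF with a JSON sidecar, MRC
# read support, and programmatic fixture generation.
#
# Reading TIFF goes through tiff::readTIFF (which handles out-of-range
# float32 samples); writing uses a minimal single-strip float32 writer,
# since the installed writers clamp float samples to [0, 1].

write_float_tiff <- function(mats, path) {
  stopifnot(is.list(mats), length(mats) >= 1)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  npages <- length(mats)
  data_bytes <- vapply(mats, function(m) 4L * length(m), integer(1))
  data_off <- 8L + c(0L, cumsum(data_bytes))[seq_len(npages)]
  ifd_size <- 2L + 10L * 12L + 4L
  ifd_off <- 8L + sum(data_bytes) + (seq_len(npages) - 1L) * ifd_size
  # header
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifd_off[1])
  # image data, row-major scanlines
  for (m in mats) {
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (p in seq_len(npages)) {
    m <- mats[[p]]
    w16(10L)
    entry(256L, 4L, 1L, ncol(m))            # ImageWidth
    entry(257L, 4L, 1L, nrow(m))            # ImageLength
    entry(258L, 3L, 1L, 32L)                # BitsPerSample
    entry(259L, 3L, 1L, 1L)                 # Compression: none
    entry(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off[p])        # StripOffsets
    entry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    entry(278L, 4L, 1L, nrow(m))            # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes[p])      # StripByteCounts
    entry(339L, 3L, 1L, 3L)                 # SampleFormat: IEEE float
    w32(if (p < npages) ifd_off[p + 1] else 0L)
  }
  invisible(path)
}

#' @rdname write_stack
#' @export
sidecar_path <- function(path) paste0(path, ".json")

#' Write a frame stack as multi-page float TIFF plus JSON sidecar
#'
#' Frames are stored as 32-bit IEEE floats in acquisition order; exposure
#' times, kinds, seeds, the quadrant layout and any ground-truth metadata
#' travel in a `<path>.json` sidecar.
#'
#' @param frames a list of `ccd_frame`s (or a stack list with elements
#'   `signal`/`dark` as from [simulate_flat_stack()], which is flattened
#'   in signal-then-dark order).
#' @param path output TIFF path.
#' @param truth optional ground-truth record stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, truth = NULL) {
  if (!is.null(frames$signal)) {
    if (is.null(truth)) truth <- frames$truth
    frames <- c(frames$signal, frames$dark)
  }
  stopifnot(all(vapply(frames, inherits, logical(1), "ccd_frame")))
  shapes <- vapply(frames, function(f) dim(f$data), integer(2))
  if (any(shapes != shapes[, 1])) stop("all frames must share one shape")
  write_float_tiff(lapply(frames, function(f) f$data), path)
  meta <- list(
    format = "ccdnoise-stack-v1",
    n_frames = length(frames),
    shape = dim(frames[[1]]$data),
    t_acq = vapply(frames, function(f) f$t_acq, numeric(1)),
    kind = vapply(frames, function(f) f$kind, character(1)),
    seed = vapply(frames, function(f) as.integer(f$seed)[1], integer(1)),
    quadrant_layout = "2x2",
    truth = truth
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a frame stack
#'
#' Reads a multi-page float TIFF written by [write_stack()] (or any float
#' TIFF with the documented sidecar), or an MRC volume read-only.  A
#' missing sidecar is an error for TIFF input; for MRC input exposure
#' times default to `NA`.
#'
#' @param path TIFF or `.mrc` path.
#' @return a list with `frames` (list of `ccd_frame`s) and `truth`
#'   (ground-truth record or `NULL`).
#' @export
read_stack <- function(path) {
  if (grepl("\\.mrc$", path, ignore.case = TRUE)) {
    mats <- read_mrc(path)
    frames <- lapply(mats, function(m) ccd_frame(m, NA_real_, "signal"))
    return(list(frames = frames, truth = NULL))
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar: expected ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_frames)
    stop(sprintf("sidecar promises %d frames, TIFF holds %d",
                 meta$n_frames, length(pages)))
  if (any(!vapply(pages, function(p) all(is.finite(p)), logical(1))))
    stop("stack contains non-finite samples")
  frames <- lapply(seq_along(pages), function(i) {
    ccd_frame(pages[[i]], meta$t_acq[i], meta$kind[i],
              seed = meta$seed[i])
  })
  list(frames = frames, truth = meta$truth)
}

# Minimal MRC (mode 2 float32 / mode 1 int16) reader, little-endian.
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 256, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  nsymbt <- hdr[24]
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5 || nz > 1e5)
    stop("not a readable MRC file (implausible dimensions)")
  seek(con, 1024 + nsymbt)
  npix <- nx * ny
  lapply(seq_len(nz), function(k) {
    v <- switch(as.character(mode),
      "2" = readBin(con, "numeric", npix, size = 4, endian = "little"),
      "1" = as.numeric(readBin(con, "integer", npix, size = 2,
                               endian = "little")),
      "0" = as.numeric(readBin(con, "integer", npix, size = 1, signed = TRUE)),
      stop("unsupported MRC mode ", mode))
    t(matrix(v, nx, ny))   # x fastest; return rows = y, cols = x
  })
}

#' Fixture configuration
#'
#' Validated parameter record for [generate_fixtures()]; unknown keys are
#' rejected.
#'
#' @param shape detector shape.
#' @param s_ref_c target flat-field intensity (counts).
#' @param t_acq reference exposure time (s).
#' @param w_ref flat/dark pairs in the gain-reference stack.
#' @param dark_exposures exposure times of the dark series (s).
#' @param ladder_counts target intensities of the non-linearity ladder.
#' @param cosmic_rate cosmic-ray events per second.
#' @param seed master seed.
#' @param ... rejected.
#' @return a named list of class `fixture_config`.
#' @export
fixture_config <- function(shape = c(256L, 256L), s_ref_c = 7050,
                           t_acq = 0.85, w_ref = 30L,
                           dark_exposures = c(0.1, 0.5, 1, 2, 4),
                           ladder_counts = seq(1000, 30000, length.out = 10),
                           cosmic_rate = 36.5, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  structure(list(shape = as.integer(shape), s_ref_c = s_ref_c,
                 t_acq = t_acq, w_ref = as.integer(w_ref),
                 dark_exposures = dark_exposures,
                 ladder_counts = ladder_counts,
                 cosmic_rate = cosmic_rate, seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate reference fixture stacks
#'
#' Emits small simulated stacks for every pipeline stage into `out_dir`:
#' a dark series over exposure times, a flat/dark gain-reference stack, an
#' intensity ladder for the non-linearity fit, a cosmic-ray-contaminated
#' frame, and a ZLP-like spike stack.  A manifest lists the files with
#' their ground truth; runs with the same master seed are bit-identical.
#'
#' @param out_dir writable output directory (created if missing).
#' @param config a [fixture_config()].
#' @param det optional [detector_model()] overriding the default.
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
generate_fixtures <- function(out_dir, config = fixture_config(),
                              det = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(det)) {
    det <- detector_model(shape = config$shape,
                          seed = derive_seed(config$seed, 99L))
  }
  beam <- beam_model(s_src = config$s_ref_c / det$g / config$t_acq)
  manifest <- list(seed = config$seed,
                   detector = list(g = det$g, beta_conv = det$beta_conv,
                                   beta_g = det$g * det$beta_conv,
                                   read_sigma = det$read_sigma,
                                   row_sigma = det$row_sigma,
                                   read_offset = det$read_offset,
                                   dark_rate = mean(det$dark_rate),
                                   sigma_qe = stats::sd(det$gain_map)),
                   files = list())
  add <- function(name, frames, truth = NULL) {
    p <- file.path(out_dir, name)
    write_stack(frames, p, truth = truth)
    manifest$files[[name]] <<- list(path = p, truth = truth)
  }
  # dark series: one pair per exposure
  darks <- list()
  for (i in seq_along(config$dark_exposures)) {
    tt <- config$dark_exposures[i]
    darks <- c(darks,
               list(simulate_dark(det, tt, derive_seed(config$seed, 1L, i, 1L)),
                    simulate_dark(det, tt, derive_seed(config$seed, 1L, i, 2L))))
  }
  add("dark_series.tif", darks,
      truth = list(exposures = config$dark_exposures))
  # gain-reference stack
  stk <- simulate_flat_stack(det, beam, config$w_ref, config$w_ref,
                             config$t_acq, derive_seed(config$seed, 2L))
  add("gain_reference_stack.tif", stk)
  # intensity ladder
  ladder <- list()
  for (i in seq_along(config$ladder_counts)) {
    bz <- beam_model(s_src = config$ladder_counts[i] / det$g / config$t_acq)
    ladder <- c(ladder,
                list(simulate_frame(det, bz, config$t_acq,
                                    derive_seed(config$seed, 3L, i, 1L)),
                     simulate_dark(det, config$t_acq,
                                   derive_seed(config$seed, 3L, i, 2L))))
  }
  add("intensity_ladder.tif", ladder,
      truth = list(targets = config$ladder_counts, nonlin = det$nonlin))
  # cosmic-ray-contaminated frame pair
  cr <- inject_cosmic_rays(
    simulate_frame(det, beam, config$t_acq, derive_seed(config$seed, 4L, 1L)),
    rate = config$cosmic_rate, seed = derive_seed(config$seed, 4L, 2L))
  add("cosmic_contaminated.tif", list(cr),
      truth = list(rate = config$cosmic_rate,
                   n_events = sum(attr(cr, "cosmic_mask"))))
  # ZLP-like spike frames: signal concentrated in a narrow band of rows
  rows <- config$shape[1]
  prof <- exp(-(seq_len(rows) - rows / 2 - 0.5)^2 / (2 * 2^2))
  smap <- matrix(prof, rows, config$shape[2])
  smap <- smap / mean(smap) * config$s_ref_c / det$g / config$t_acq / 4
  zbeam <- beam_model(s_src = smap)
  zlp <- lapply(1:4, function(k)
    simulate_frame(det, zbeam, config$t_acq, derive_seed(config$seed, 5L, k)))
  add("zlp_spike.tif", zlp, truth = list(band_sigma_rows = 2))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
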