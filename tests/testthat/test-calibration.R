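# Calibration pipeline: artifact removal, dark subtraction, noise
# decomposition, gain reference, k_ref and smoothed-gain estimators.

test_that("cosmic-ray removal flags spikes and guards against contamination", {
  set.seed(20)
  x <- matrix(rnorm(128^2, 100, 4), 128, 128)
  spike <- x; spike[40, 60] <- 100 + 12 * 4
  cr <- remove_cosmic_rays(ccd_frame(spike, 1))
  expect_true(cr$mask[40, 60])
  expect_equal(sum(cr$mask), 1)
  # spike and its 3x3 neighbourhood replaced by the robust mean
  expect_lt(abs(cr$frame$data[40, 60] - 100), 0.5)
  expect_lt(abs(cr$frame$data[41, 61] - 100), 0.5)
  # spike-free Gaussian frame: expected false positives 2*phi(-5)*n ~ 0.01
  cr0 <- remove_cosmic_rays(ccd_frame(x, 1))
  expect_lte(sum(cr0$mask), 1)
  # heavy contamination errors
  bad <- x; bad[1:40, 1:15] <- 1e5
  expect_error(remove_cosmic_rays(ccd_frame(bad, 1)), "contaminated")
})

test_that("detected cosmic-ray counts grow linearly with exposure", {
  det <- test_detector(shape = c(128L, 128L))
  rate <- 40
  counts <- vapply(c(0.5, 1, 2), function(tt) {
    b <- flat_beam(det, 3000, tt)
    mean(vapply(1:6, function(k) {
      f <- inject_cosmic_rays(simulate_frame(det, b, tt, 300 + k),
                              rate = rate, seed = 500 + k + 100 * tt)
      sum(remove_cosmic_rays(f, max_frac = 0.05)$mask)
    }, numeric(1)))
  }, numeric(1))
  fit <- lm(counts ~ c(0.5, 1, 2))
  expect_equal(unname(coef(fit)[2]), rate, tolerance = 0.25)
})

test_that("dark subtraction clears the offset and doubles detector noise", {
  det <- test_detector(shape = c(64L, 64L))
  d1 <- simulate_dark(det, 0.5, 1)
  expect_true(all(dark_subtract(d1, d1)$data == 0))
  expect_error(dark_subtract(d1, simulate_dark(det, 1, 2)), "exposure")
  det0 <- test_detector(shape = c(64L, 64L), row_sigma = 0)
  nf <- 30
  vv <- mm <- numeric(nf)
  for (k in seq_len(nf)) {
    ds <- dark_subtract(simulate_dark(det0, 0.5, 2 * k),
                        simulate_dark(det0, 0.5, 2 * k + 1))
    vv[k] <- var(as.vector(ds$data))
    mm[k] <- mean(ds$data)
  }
  sd2 <- 16 + mean(det0$dark_rate) * 0.5
  expect_lt(abs(mean(mm)), 3 * sqrt(2 * sd2 / (nf * 64^2)))
  expect_lt(abs(mean(vv) - 2 * sd2), 3 * sd(vv) / sqrt(nf))
})

test_that("row splitting is exact and recovers integer offsets", {
  set.seed(21)
  x <- matrix(rnorm(64^2, 0, 0.3), 64, 64)
  off <- matrix(0, 64, 64)
  q <- quadrant_ranges(c(64, 64))
  truth <- list()
  for (nm in names(q)) {
    ro <- sample(c(-1L, 0L, 2L), length(q[[nm]]$rows), replace = TRUE)
    off[q[[nm]]$rows, q[[nm]]$cols] <-
      off[q[[nm]]$rows, q[[nm]]$cols] + ro
    truth[[nm]] <- ro
  }
  sp <- split_row_noise(ccd_frame(x + off, 1))
  expect_equal(sp$row_offsets, truth, ignore_attr = TRUE)
  # decomposition reassembles bit-exactly
  expect_identical(sp$residual$data + sp$offsets$data, x + off)
  # mis-rounding probability: at row-mean SD 0.126 the one-sided tail
  # beyond 0.5 is about 3.6e-5
  expect_equal(pnorm(-0.5, 0, 0.126), 3.65e-5, tolerance = 0.02)
})

test_that("row splitting after dark subtraction commutes with quadrant slicing", {
  det <- test_detector(shape = c(64L, 64L))
  ds <- dark_subtract(simulate_dark(det, 0.5, 51), simulate_dark(det, 0.5, 52))
  sp <- split_row_noise(ds)
  q <- quadrant_ranges(c(64, 64))
  for (nm in names(q)) {
    sub <- ds$data[q[[nm]]$rows, q[[nm]]$cols]
    # quadrant occupies full rows of its own sub-frame: per-row means match
    ro <- sign(rowMeans(sub)) * floor(abs(rowMeans(sub)) + 0.5)
    expect_equal(unname(sp$row_offsets[[nm]]), unname(ro))
  }
})

test_that("exposure regression separates read-out and thermal noise", {
  det <- test_detector(shape = c(128L, 128L), dark_rate = 1.2)
  frames <- list()
  i <- 0
  for (tt in c(0.2, 0.5, 1, 2, 4)) {
    for (r in 1:4) {
      i <- i + 1
      frames[[i]] <- dark_subtract(simulate_dark(det, tt, 1000 + 10 * i),
                                   simulate_dark(det, tt, 1000 + 10 * i + 1))
    }
  }
  nb <- regress_read_thermal(frames)
  expect_equal(unname(mean(nb$read_var)), 16, tolerance = 0.05)
  expect_equal(unname(mean(nb$dark_rate_var)), 1.2, tolerance = 0.25)
  # realized integer row offsets have variance ~0.44 counts^2
  expect_equal(unname(mean(nb$row_var)), 0.442, tolerance = 0.2)
  expect_error(regress_read_thermal(frames[1:2]), ">= 3")
  # zero dark current: slope consistent with zero
  det0 <- test_detector(shape = c(64L, 64L), dark_rate = 0)
  f0 <- list()
  i <- 0
  for (tt in c(0.2, 1, 2, 4)) for (r in 1:3) {
    i <- i + 1
    f0[[i]] <- dark_subtract(simulate_dark(det0, tt, 3000 + 10 * i),
                             simulate_dark(det0, tt, 3000 + 10 * i + 1))
  }
  nb0 <- suppressWarnings(regress_read_thermal(f0))
  expect_true(all(nb0$dark_ci[, 1] <= 0 & nb0$dark_ci[, 2] >= 0))
  # combined budget assembles additively
  s2 <- sigma_d2(nb, t_acq = 2)
  expect_equal(unname(s2), unname(nb$read_var + nb$row_var +
                                    2 * nb$dark_rate_var))
})

test_that("gain-reference-normalized noise scales by the reference factor", {
  rc <- ref_stack_128()
  det <- rc$det; ref <- rc$ref
  frames <- raw <- list()
  i <- 0
  for (tt in c(0.2, 1, 2, 4)) for (r in 1:4) {
    i <- i + 1
    ds <- dark_subtract(simulate_dark(det, tt, 5000 + 10 * i),
                        simulate_dark(det, tt, 5000 + 10 * i + 1))
    raw[[i]] <- ds
    frames[[i]] <- apply_gain_reference(ds, ref)
  }
  nb_raw <- regress_read_thermal(raw)
  nb_ref <- regress_read_thermal(frames, ref = ref)
  # after dividing out the reference factor both report detector-domain
  # variances
  expect_equal(unname(nb_ref$read_var), unname(nb_raw$read_var),
               tolerance = 0.03)
  # without the correction the measured variance is inflated by the factor
  nb_unc <- regress_read_thermal(frames)
  expect_gt(mean(nb_unc$read_var / nb_raw$read_var), 1.005)
})

test_that("gain reference construction recovers the fixed pattern", {
  det <- test_detector(shape = c(64L, 64L))
  # noiseless synthetic pair: signal = map * C + offset, dark = offset
  C <- 5000
  sig <- ccd_frame(det$gain_map * C + 252, 1)
  drk <- ccd_frame(matrix(252, 64, 64), 1)
  ref <- build_gain_reference(list(sig), list(drk), clean = FALSE,
                              estimate_uncertainty = FALSE)
  expect_equal(ref$map, det$gain_map, tolerance = 1e-12)
  expect_equal(mean(ref$map), 1, tolerance = 1e-12)
  # simulated stack: map correlates with truth at the k_ref-limited level
  rc <- ref_stack_128()
  expect_gt(cor(as.vector(rc$ref$map), as.vector(rc$det$gain_map)), 0.99)
  resid_sd <- sd(rc$ref$map - rc$det$gain_map)
  kth <- kref_theoretical(rc$ref$s_ref_c, rc$det$g, rc$det$beta_conv,
                          16 + 0.36 + 1.02, w = rc$ref$w)
  expect_equal(resid_sd, kth, tolerance = 0.1)
  expect_equal(mean(rc$ref$map), 1, tolerance = 1e-9)
})

test_that("theoretical k_ref obeys its scaling laws and its smoothed-gain inversion", {
  k1 <- kref_theoretical(7050, g = 14, beta = 0.11, sigma_d2 = 17.4, w = 1)
  k30 <- kref_theoretical(7050, g = 14, beta = 0.11, sigma_d2 = 17.4, w = 30)
  expect_equal(k30^2, k1^2 / 30, tolerance = 1e-12)
  # inversion returns the smoothed gain
  bg <- smoothed_gain_from_kref(7050, k30, sigma_d2 = 17.4, w = 30)
  expect_equal(bg, 14 * 0.11, tolerance = 1e-10)
  # pure-Poisson limit
  k0 <- kref_theoretical(7050, 14, 0.11, sigma_d2 = 0, w = 4)
  expect_equal(k0^2, 14 * 0.11 / (4 * 7050), tolerance = 1e-12)
})

test_that("the two k_ref estimators agree with each other and with theory", {
  rc <- ref_stack_128()
  det <- rc$det; stk <- rc$stk
  kth <- kref_theoretical(rc$ref$s_ref_c, det$g, det$beta_conv,
                          16 + 0.36 + 1.02, w = 16)
  expect_equal(rc$ref$k_ref, kth, tolerance = 0.05)
  # difference-of-references estimator on two half stacks (w = 8 each)
  refA <- build_gain_reference(stk$signal[1:8], stk$dark[1:8],
                               estimate_uncertainty = FALSE)
  refB <- build_gain_reference(stk$signal[9:16], stk$dark[9:16],
                               estimate_uncertainty = FALSE)
  kdiff <- estimate_kref_difference(refA, refB)
  kauto <- estimate_kref_autocov(
    Map(dark_subtract, stk$signal, stk$dark), stk$dark,
    sigma_ref_all = rc$ref$sigma_ref)
  k8 <- kref_theoretical(rc$ref$s_ref_c, det$g, det$beta_conv,
                         16 + 0.36 + 1.02, w = 8)
  expect_equal(kdiff, k8, tolerance = 0.05)
  # cross-check: same w, the two estimation routes agree closely
  expect_equal(kauto$k_ref * sqrt(16 / 8), kdiff, tolerance = 0.03)
  expect_equal(refA$map, refB$map, tolerance = 0.05)
  expect_equal(estimate_kref_difference(refA, refA), 0)
  expect_error(estimate_kref_difference(rc$ref, refA), "different numbers")
  # recovered reference correlation matches the PSF autocorrelation core
  rho_psf <- pearson_from_kernel(det$psf)
  ctr_e <- kauto$rho$center; ctr_t <- rho_psf$center
  expect_equal(kauto$rho$field[ctr_e[1] + (-2:2), ctr_e[2]],
               rho_psf$field[ctr_t[1] + (-2:2), ctr_t[2]],
               tolerance = 0.15)
})

test_that("smoothed gain is recovered within 2% and is internally consistent", {
  rc <- ref_stack_128()
  det <- rc$det; beam <- rc$beam
  sig <- lapply(1:8, function(k) simulate_frame(det, beam, 0.85,
                                                derive_seed(7100, k)))
  drk <- lapply(1:10, function(k) simulate_dark(det, 0.85,
                                                derive_seed(7200, k)))
  flats <- Map(dark_subtract, sig, drk[1:8])
  dd <- list(dark_subtract(drk[[9]], drk[[10]]))
  sg <- estimate_smoothed_gain(flats, rc$ref, dd)
  truth <- det$g * det$beta_conv
  expect_equal(sg$beta_g, truth, tolerance = 0.02)
  # inverting the same stack's k_ref returns a consistent smoothed gain
  bg_k <- smoothed_gain_from_kref(rc$ref$s_ref_c, rc$ref$k_ref,
                                  sigma_d2 = 0, w = rc$ref$w)
  expect_equal(bg_k, sg$beta_g, tolerance = 0.03)
})

test_that("a delta-PSF detector yields beta*g equal to the plain gain", {
  det <- detector_model(shape = c(128L, 128L), g = 5,
                        psf = ccd_kernel(matrix(1, 1, 1), "sum"),
                        seed = 77L)
  beam <- flat_beam(det, 6000, 0.85)
  stk <- simulate_flat_stack(det, beam, 12L, 12L, 0.85, seed = 901L)
  ref <- build_gain_reference(stk$signal, stk$dark)
  sig <- lapply(1:6, function(k) simulate_frame(det, beam, 0.85,
                                                derive_seed(7300, k)))
  drk <- lapply(1:8, function(k) simulate_dark(det, 0.85,
                                               derive_seed(7400, k)))
  sg <- estimate_smoothed_gain(Map(dark_subtract, sig, drk[1:6]), ref,
                               list(dark_subtract(drk[[7]], drk[[8]])))
  expect_equal(sg$beta_g, 5, tolerance = 0.03)
})

test_that("gain normalization removes the fixed pattern and rescales noise", {
  rc <- ref_stack_128()
  det <- rc$det; ref <- rc$ref
  ones <- ref
  ones$map <- matrix(1, 128, 128); ones$recip <- ones$map
  f <- dark_subtract(simulate_frame(det, rc$beam, 0.85, 8101),
                     simulate_dark(det, 0.85, 8102))
  expect_equal(apply_gain_reference(f, ones)$data, f$data)
  # fixed-pattern variance removed down to the k_ref-limited floor
  v_raw <- var(as.vector(f$data))
  v_norm <- var(as.vector(apply_gain_reference(f, ref)$data))
  s_c <- mean(f$data)
  pattern <- sd(det$gain_map)^2 * s_c^2
  expect_lt(v_norm, v_raw - 0.8 * pattern)
  # dark-only input: SD inflated by sqrt(phi^-2 + sigma_ref^2/phi^4)
  nf <- 25
  ratio <- vapply(seq_len(nf), function(k) {
    d <- split_row_noise(dark_subtract(simulate_dark(det, 0, 8200 + 2 * k),
                                       simulate_dark(det, 0, 8201 + 2 * k)))$residual
    dn <- apply_gain_reference(d, ref)
    sd(as.vector(dn$data)) / sd(as.vector(d$data))
  }, numeric(1))
  expect_equal(mean(ratio), sqrt(mean(gain_ref_noise_scale(ref))),
               tolerance = 0.01)
})
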