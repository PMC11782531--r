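# Post-binning, noise propagation under binning, and the EELS model.

test_that("post_bin sums blocks, discards leftovers and conserves counts", {
  x <- matrix(1, 4, 4)
  b <- post_bin(x, H = 2, V = 2)
  expect_equal(b, matrix(4, 2, 2))
  # 2048-wide frame, H = 600: 3 binned columns, 248 columns discarded
  wide <- matrix(1, 2, 2048)
  b6 <- post_bin(wide, H = 600, V = 1)
  expect_equal(ncol(b6), 3L)
  expect_equal(sum(b6), 2 * 1800)
  # count conservation over the retained region
  set.seed(30)
  y <- matrix(rnorm(64 * 60), 64, 60)
  bb <- post_bin(y, H = 7, V = 3)
  expect_equal(sum(bb), sum(y[1:63, 1:56]), tolerance = 1e-12)
  both <- post_bin(y, H = 7, V = 3, anchor = "average-both")
  expect_equal(sum(both$back), sum(y[2:64, 5:60]), tolerance = 1e-12)
  fr <- ccd_frame(y, 1)
  expect_s3_class(post_bin(fr, 2, 2), "ccd_frame")
})

test_that("alpha distribution factor follows its limits", {
  expect_equal(alpha_factor(c(5, 0, 0, 0)), 1)
  expect_equal(alpha_factor(matrix(1, 3, 4)), 1 / 12)
  expect_equal(alpha_factor(c(2, 2)), 0.5)
  expect_equal(alpha_factor(matrix(1, 3, 4), normalized = TRUE), 1)
  expect_error(alpha_factor(c(0, 0)), "no signal")
  # concentrated ZLP-like profile far exceeds flat illumination
  prof <- exp(-(1:260 - 130)^2 / (2 * 2.5^2))
  expect_gt(alpha_factor(prof) / alpha_factor(rep(1, 260)), 20)
})

test_that("binned k_ref reduces to the unbinned theory and scales with 1/(HV)", {
  delta <- matrix(0, 41, 41); delta[21, 21] <- 1
  rho_d <- pearson_field(delta, c(128, 128))
  k11 <- binned_kref(7050, w = 30, beta_g = 1.55, sigma_d2 = 17.4,
                     rho_ref = rho_d, H = 1, V = 1)
  expect_equal(k11, kref_theoretical(7050, 1.55, 1, 17.4, 30),
               tolerance = 1e-12)
  # delta correlation: k^2 scales as 1/(HV) in the Poisson-dominated regime
  k44 <- binned_kref(7050, w = 30, beta_g = 1.55, sigma_d2 = 0,
                     rho_ref = rho_d, H = 4, V = 4)
  k11p <- binned_kref(7050, w = 30, beta_g = 1.55, sigma_d2 = 0,
                      rho_ref = rho_d, H = 1, V = 1)
  expect_equal(k44^2, k11p^2 / 16, tolerance = 1e-12)
})

test_that("predicted binned variance reduces to the photon-transfer relation at H=V=1", {
  s <- matrix(7050, 8, 8)
  pv <- predict_binned_variance(s, H = 1, V = 1, k_binned = 0.0027,
                                beta_g_binned = 1.55, beta_bf_binned = 0.99,
                                sigma_d_corr2 = c(pix = 17, row = 0.45))
  direct <- total_variance_model(7050, 0.0027, 1.55, 0.99, 17 + 0.45)
  expect_equal(pv[1, 1], direct, tolerance = 1e-12)
})

test_that("pure row noise grows quadratically under horizontal binning", {
  det <- test_detector(shape = c(128L, 128L), read_sigma = 0,
                       dark_rate = 0, row_sigma = 0.6)
  vH <- vapply(c(1, 2, 4, 8), function(H) {
    mean(vapply(1:12, function(k) {
      ds <- dark_subtract(simulate_dark(det, 0, 6000 + 2 * k),
                          simulate_dark(det, 0, 6001 + 2 * k))
      q <- quadrant_ranges(c(128, 128))
      mean(vapply(q, function(z) {
        var(as.vector(post_bin(ds$data[z$rows, z$cols], H = H, V = 1)))
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  ratio <- vH / vH[1]
  expect_equal(ratio, c(1, 4, 16, 64), tolerance = 0.05)
})

test_that("empirical binned variances match the noise model across H, V", {
  # within-frame sample variances of gain-normalized simulated frames,
  # against the model prediction corrected for finite-frame correlation
  det <- detector_model(shape = c(256L, 256L))
  beam <- flat_beam(det, 7050, 0.85)
  stk <- simulate_flat_stack(det, beam, 24L, 24L, 0.85, seed = 61L)
  ref <- build_gain_reference(stk$signal, stk$dark)
  sig <- lapply(1:20, function(k) simulate_frame(det, beam, 0.85,
                                                 derive_seed(6100, k)))
  drk <- lapply(1:20, function(k) simulate_dark(det, 0.85,
                                                derive_seed(6200, k)))
  xs <- Map(function(s, d) apply_gain_reference(dark_subtract(s, d), ref),
            sig, drk)
  roff <- unlist(c(lapply(sig, function(f) f$truth$row_offsets),
                   lapply(drk, function(f) f$truth$row_offsets)))
  srow2 <- mean(roff^2)
  pix <- 16 + 1.2 * 0.85
  rho_psf <- pearson_from_kernel(det$psf)
  beta_g <- det$g * det$beta_conv
  qr <- quadrant_ranges(det$shape)
  s_c <- mean(vapply(xs, function(f) mean(f$data), numeric(1)))
  scale_all <- mean(gain_ref_noise_scale(ref))
  for (hv in list(c(3, 3), c(4, 1), c(1, 4))) {
    H <- hv[1]; V <- hv[2]
    bp <- bin_pearson(rho_psf, H = H, V = V)
    bg_hv <- beta_g * bp$rho00_star / (H * V)
    kb <- binned_kref(ref$s_ref_c, ref$w, beta_g, pix + 0.36, ref$rho_ref,
                      H = H, V = V)
    sgrid <- matrix(s_c, 128 %/% V * V, 128 %/% H * H)
    pv <- predict_binned_variance(sgrid, H = H, V = V, k_binned = kb,
                                  beta_g_binned = bg_hv,
                                  sigma_d_corr2 = c(pix = pix * scale_all,
                                                    row = srow2 * scale_all))[1, 1]
    # within-frame correction: beta_corr of the binned total correlation
    rps <- resize_centred(rho_psf$field, 20, 20)
    Kt <- beta_g * s_c * rps + ref$k_ref^2 * s_c^2 * rps
    Kt[21, 21] <- Kt[21, 21] + 2 * pix * scale_all
    Kt[21, ] <- Kt[21, ] + 2 * srow2 * scale_all
    rt <- pearson_field(Kt / Kt[21, 21], c(128, 128))
    bc <- beta_corr(bin_pearson(rt, H = H, V = V)$rho_bin,
                    128 %/% V, 128 %/% H)
    pred <- pv * bc
    per_frame <- vapply(xs, function(f) {
      mean(vapply(qr, function(z) {
        b <- post_bin(f$data[z$rows, z$cols], H = H, V = V,
                      anchor = "average-both")
        (var(as.vector(b$front)) + var(as.vector(b$back))) / 2
      }, numeric(1)))
    }, numeric(1))
    se <- sd(per_frame) / sqrt(length(per_frame))
    expect_lt(abs(mean(per_frame) - pred), 3 * se)
  }
})

test_that("EELS variance model matches Monte-Carlo channel statistics", {
  det <- test_detector(shape = c(128L, 128L))
  V <- 64L
  # ZLP-like band: Gaussian row profile centred on the EELS region
  rows <- det$shape[1]
  prof <- exp(-(seq_len(rows) - rows / 2 - 0.5)^2 / (2 * 4^2))
  target <- 2e5 / sum(prof)      # ~2e5 counts per channel after summation
  smap <- matrix(prof * target, rows, det$shape[2]) / det$g / 0.85
  beam <- beam_model(s_src = smap)
  band <- (rows / 2 - V / 2 + 1):(rows / 2 + V / 2)
  ref0 <- structure(list(map = det$gain_map, recip = 1 / det$gain_map, w = 1,
                         s_ref_c = 7050,
                         phi = quadrant_mean(det$gain_map),
                         sigma_ref = sd(det$gain_map), k_ref = 0,
                         rho_ref = NULL, sigma_qe = sd(det$gain_map)),
                    class = "gain_reference")
  nf <- 60
  specs <- vapply(seq_len(nf), function(k) {
    s <- simulate_frame(det, beam, 0.85, derive_seed(6500, k))
    d <- simulate_dark(det, 0.85, derive_seed(6600, k))
    x <- apply_gain_reference(dark_subtract(s, d), ref0)
    colSums(x$data[band, ])
  }, numeric(det$shape[2]))
  emp_var <- apply(specs, 1, var)
  # model prediction from ground truth
  rho_psf <- pearson_from_kernel(det$psf)
  bp <- bin_pearson(rho_psf, H = 1, V = V)
  beta_eels <- det$beta_conv * bp$rho00_star / V
  exp_counts <- matrix(prof * target, rows, det$shape[2])[band, ]
  scale_all <- mean(gain_ref_noise_scale(ref0))
  srow2 <- 0.442
  side <- V * (16 + 1.2 * 0.85 + srow2) * scale_all
  em <- eels_model(V = V, g = det$g, beta_eels = beta_eels,
                   kref_binned = 0,
                   sigma_d_sets = c(left = side, right = side))
  pred <- eels_variance_model(exp_counts, em)
  # channel-averaged agreement within 3 SE of the Monte-Carlo mean
  se <- sd(emp_var / pred$variance) / sqrt(ncol(specs) / 4)  # PSF-correlated
  expect_lt(abs(mean(emp_var / pred$variance) - 1), 3 * se)
  # alpha behaviour: concentrated ZLP alpha far above flat
  a_zlp <- alpha_factor(exp_counts[, 1], normalized = TRUE)
  expect_gt(a_zlp, 3)
})

test_that("compose_zlp convolves component kernels", {
  d <- delta_kernel()
  zd <- compose_zlp(d, d, d)$omega
  ctr <- (dim(zd) + 1L) %/% 2L
  expect_equal(zd[ctr[1], ctr[2]], 1)
  expect_equal(sum(zd), 1, tolerance = 1e-9)
  g1 <- gaussian_kernel(1.0, radius = 6)
  g2 <- gaussian_kernel(1.5, radius = 8)
  z <- compose_zlp(g1, g2, delta_kernel())
  # Gaussian components: widths add in quadrature
  ctr <- (dim(z$omega) + 1L) %/% 2L
  prof <- z$omega[ctr[1], ]
  i <- seq_along(prof) - ctr[2]
  s_eff <- sqrt(sum(i^2 * prof) / sum(prof))
  expect_equal(s_eff, sqrt(1 + 1.5^2), tolerance = 0.02)
  # asymmetric dispersion kernels are preserved, not symmetrized
  asym <- ccd_kernel(matrix(c(0.6, 0.3, 0.1), 1), "sum")
  za <- compose_zlp(delta_kernel(), asym, delta_kernel())
  ctr <- (dim(za$omega) + 1L) %/% 2L
  expect_false(isTRUE(all.equal(za$omega[ctr[1], ctr[2] - 1],
                                za$omega[ctr[1], ctr[2] + 1])))
})
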