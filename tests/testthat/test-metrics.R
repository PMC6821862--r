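test_that("split_projections partitions the angle set into two half-scans", {
  g <- acquisition_geometry(512)
  st <- projection_stack(array(seq_len(512 * 4 * 4), dim = c(512, 4, 4)), g)
  halves <- split_projections(st)
  expect_equal(halves$a$geometry$n_projections, 256)
  expect_equal(halves$b$geometry$n_projections, 256)
  aa <- projection_angles(halves$a$geometry)
  ab <- projection_angles(halves$b$geometry)
  expect_length(intersect(aa, ab), 0)
  expect_equal(sort(c(aa, ab)), projection_angles(g))
  expect_equal(aa[2] - aa[1], 2 * 360 / 512)  # doubled step, full range
})

test_that("split halves match a brute-force index-slicing oracle", {
  g <- acquisition_geometry(8)
  set.seed(3)
  data <- array(rnorm(8 * 5 * 6), dim = c(8, 5, 6))
  st <- projection_stack(data, g)
  halves <- split_projections(st)
  expect_identical(halves$a$data, data[c(1, 3, 5, 7), , ])
  expect_identical(halves$b$data, data[c(2, 4, 6, 8), , ])
  expect_error(split_projections(
    projection_stack(data[1:7, , ], acquisition_geometry(7))),
    class = "optomo_value_error")
})

test_that("FRC of an image with itself is 1 in every ring", {
  set.seed(21)
  img <- matrix(rnorm(64 * 64), 64)
  f <- frc_curve(img, img)
  expect_true(all(abs(f$frc[is.finite(f$frc)] - 1) < 1e-12))
  # symmetry and scale invariance
  img2 <- matrix(rnorm(64 * 64), 64)
  f12 <- frc_curve(img, img2)
  f21 <- frc_curve(img2, img)
  expect_equal(f12$frc, f21$frc)
  f_scaled <- frc_curve(img, 3.7 * img2)
  expect_equal(f12$frc, f_scaled$frc, tolerance = 1e-12)
  # DC ring equals 1 for equal nonzero means (no mean subtraction)
  fd <- frc_curve(img + 5, img2 + 5, mean_subtract = FALSE, apodize = FALSE)
  expect_equal(fd$frc[1], 1, tolerance = 1e-6)
})

test_that("independent white noise decorrelates above 0.1 cycles/px", {
  set.seed(22)
  a <- matrix(rnorm(256^2), 256)
  b <- matrix(rnorm(256^2), 256)
  f <- frc_curve(a, b)
  hi <- f$freq_cyc_per_px > 0.1
  expect_lt(abs(mean(f$frc[hi], na.rm = TRUE)), 0.05)
  expect_error(frc_curve(a, matrix(0, 128, 128)),
               class = "optomo_geometry_error")
  expect_error(frc_curve(matrix(0, 16, 16), matrix(0, 16, 16)),
               class = "optomo_value_error")
})

test_that("a constructed 5 px band limit is recovered within 15%", {
  n <- 256
  set.seed(23)
  base <- matrix(rnorm(n^2), n)
  FB <- stats::fft(base)
  fr <- c(0:(n / 2), seq.int(-n / 2 + 1, -1)) / n
  R <- sqrt(outer(fr^2, fr^2, `+`))
  FB[R > 0.2] <- 0  # hard cutoff at 0.2 cyc/px = 5 px
  sig <- Re(stats::fft(FB, inverse = TRUE)) / n^2
  sig <- sig / stats::sd(sig)
  i1 <- sig + 0.35 * matrix(rnorm(n^2), n)
  i2 <- sig + 0.35 * matrix(rnorm(n^2), n)
  f <- frc_curve(i1, i2)
  expect_true(f$reached)
  expect_lt(abs(f$resolution_px - 5) / 5, 0.15)
})

test_that("noiseless split-half FRC resolution sits at the sampling floor", {
  ph <- make_phantom("disks", c(8, 64, 64))
  fp <- forward_project(ph, acquisition_geometry(128))
  f <- frc_resolution_from_halves(fp$stack, rows_sample = 4,
                                  pixel_size_um = 10)
  expect_true(!f$reached || f$resolution_px <= 4)
  if (f$reached) expect_equal(f$resolution_um, f$resolution_px * 10)
})

test_that("split-half FRC resolution degrades as projection noise grows", {
  ph <- make_phantom("disks", c(8, 64, 64))
  res <- vapply(c(0.5, 2, 6), function(sigma) {
    fp <- forward_project(ph, acquisition_geometry(64),
                          artifact_spec(noise = "gaussian",
                                        noise_param = sigma, noise_seed = 13))
    f <- frc_resolution_from_halves(fp$stack, rows_sample = 4)
    if (f$reached) f$resolution_px else Inf
  }, numeric(1))
  expect_true(all(diff(res) >= 0))
  expect_true(is.finite(res[2]))
})

test_that("profile FWHM matches analytic Gaussian and rectangular widths", {
  nr <- 64; nc <- 64
  ridge <- outer(rep(1, nr), exp(-((0:(nc - 1)) - 31.5)^2 / (2 * 9)))
  w <- profile_fwhm(ridge, c(32, 4), c(32, 59))
  expect_lt(abs(w - 2.3548 * 3), 0.2)
  rect <- matrix(0, nr, nc); rect[, 28:36] <- 1  # 9 px wide
  wr <- profile_fwhm(rect, c(20, 2), c(20, 61))
  expect_lt(abs(wr - 9), 0.5)
  expect_error(profile_fwhm(matrix(1, 32, 32), c(5, 1), c(5, 30)),
               class = "optomo_value_error")
  expect_error(profile_fwhm(matrix(1, 32, 32), c(-1, 0), c(5, 30)),
               class = "optomo_value_error")
})

test_that("a reconstructed bead is never sharper than its phantom", {
  fp <- sim_bead_scan(128, size = c(16, 48, 48), bead_dy = 0, bead_dx = 8,
                      radius = 2)
  truth <- matrix(fp$phantom$voxels[8, , ], 48, 48)
  rec <- fbp_slice(create_sinograms(fp$stack, rows = 7)[[1]],
                   filter_spec("ramp"))
  row <- 23.5 + 0  # bead row in the slice
  w_truth <- profile_fwhm(truth, c(24, 16), c(24, 47))
  w_rec <- profile_fwhm(rec, c(24, 16), c(24, 47))
  expect_gte(w_rec, w_truth - 0.05)
})

test_that("roi_stats computes snr and br; rejects degenerate masks", {
  img <- matrix(0, 20, 20)
  sig <- matrix(FALSE, 20, 20); sig[5:8, 5:8] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[14:17, 14:17] <- TRUE
  img[sig] <- 10
  img[bg] <- 2 + rep(c(-1, 1), 8)  # mean 2, sd 1 (approximately)
  rs <- roi_stats(img, sig, bg)
  expect_equal(rs$mean_signal, 10)
  expect_equal(rs$mean_background, 2)
  expect_equal(rs$snr, (10 - 2) / rs$sd_background)
  expect_equal(rs$br, 0.2)
  # identically distributed signal and background: snr ~ 0
  set.seed(8)
  img2 <- matrix(rnorm(400, 5, 1), 20, 20)
  rs2 <- roi_stats(img2, sig, bg)
  expect_lt(abs(rs2$snr), 1)
  expect_error(roi_stats(img, sig, sig), class = "optomo_value_error")
  expect_error(roi_stats(matrix(1, 20, 20), sig, bg),
               class = "optomo_value_error")
})

test_that("a 2.5-fold label-density gain yields a 2.5-fold SNR gain", {
  # constructed emission scenario: same optics/noise, specific labelling
  # 2.5x brighter over the same autofluorescence floor
  make_recon <- function(density) {
    ph <- make_phantom("disks", c(8, 64, 64),
                       disks = data.frame(cy = 0, cx = 0, r = 10,
                                          value = density))
    fp <- forward_project(ph, acquisition_geometry(128,
                                                   modality = "eOPT"),
                          artifact_spec(noise = "gaussian", noise_param = 1,
                                        noise_seed = 5))
    fbp_slice(create_sinograms(fp$stack, rows = 4)[[1]], filter_spec("ramp"))
  }
  c0 <- detector_center_col(64)
  rr <- sqrt(outer((0:63 - c0)^2, (0:63 - c0)^2, `+`))
  sig <- rr <= 6
  bg <- rr >= 16 & rr <= 26
  s1 <- roi_stats(make_recon(1), sig, bg)
  s2 <- roi_stats(make_recon(2.5), sig, bg)
  expect_lt(abs(s2$snr / s1$snr - 2.5), 0.3)
})
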