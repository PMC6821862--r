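gauss_blob <- function(nr, nc, r0, c0, sigma = 2.5, value = 100,
                       oversample = 1L) {
  os <- oversample
  rr <- (rep(seq_len(nr * os), times = nc * os) - 1) / os - (os - 1) / (2 * os)
  cc <- (rep(seq_len(nc * os), each = nr * os) - 1) / os - (os - 1) / (2 * os)
  img <- value * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
  img <- matrix(img, nr * os, nc * os)
  if (os == 1L) return(img)
  dim(img) <- c(os, nr, os, nc)
  apply(img, c(2, 4), mean)
}

test_that("detect_fiducial finds symmetric and sub-pixel blob centers", {
  img <- gauss_blob(80, 60, 40, 25)
  hit <- detect_fiducial(img)
  expect_lt(abs(hit["x"] - 25), 0.05)
  expect_lt(abs(hit["y"] - 40), 0.05)
  sub <- gauss_blob(80, 60, 40.3, 25.7, oversample = 4L)
  hit2 <- detect_fiducial(sub)
  expect_lt(abs(hit2["x"] - 25.7), 0.1)
  expect_lt(abs(hit2["y"] - 40.3), 0.1)
})

test_that("detect_fiducial flags blanks and rejects bad rois without throwing", {
  expect_null(detect_fiducial(matrix(0, 32, 32)))
  expect_error(detect_fiducial(matrix(0, 32, 32), roi = c(0, 0, 0, 5)),
               class = "optomo_value_error")
  expect_error(detect_fiducial(matrix(0, 32, 32), roi = c(20, 20, 20, 20)),
               class = "optomo_value_error")
  # dark polarity: bead absorbs against a bright background
  img <- 100 - gauss_blob(64, 64, 30, 22)
  hit <- detect_fiducial(img, polarity = "dark")
  expect_lt(abs(hit["x"] - 22), 0.1)
})

test_that("track follows the analytic circular trace", {
  fp <- sim_bead_scan(96, bead_dy = 10, bead_dx = 18)
  tr <- track_fiducial(fp$stack, full_roi(fp$stack))
  expect_true(all(tr$ok))
  o <- trace_point_oracle(0, 10, 18, tr$angle_deg)
  expect_lt(rmse(tr$x_px, o$col + detector_center_col(64)), 0.3)
})

test_that("tracking a mostly-missing bead raises a tracking error", {
  fp <- sim_bead_scan(40)
  data <- fp$stack$data
  data[16:40, , ] <- 0  # bead removed from >20% of projections
  broken <- projection_stack(data, fp$stack$geometry)
  expect_error(track_fiducial(broken, full_roi(fp$stack)),
               class = "optomo_tracking_error")
})

test_that("jittered track minus injected shifts matches the clean track", {
  fp <- sim_bead_scan(128)
  clean <- track_fiducial(fp$stack, full_roi(fp$stack))
  jj <- inject_jitter(fp$stack, 2, 7)
  tr <- track_fiducial(jj$stack, full_roi(fp$stack))
  expect_lt(rmse(tr$x_px - jj$shifts, clean$x_px), 0.3)
})

test_that("fit_sinusoid recovers a noiseless model to 1e-9 and a constant", {
  th <- (0:63) * 360 / 64
  v <- 3 * cos((th + 40) * pi / 180) + 10
  f <- fit_sinusoid(th, v)
  expect_lt(abs(f$amplitude_px - 3), 1e-9)
  expect_lt(abs(f$phase_deg - 40), 1e-9)
  expect_lt(abs(f$mean_px - 10), 1e-9)
  expect_equal(v, f$fitted_px + f$residuals_px)  # exact reconstruction
  fc <- fit_sinusoid(th, rep(7, 64))
  expect_lt(fc$amplitude_px, 1e-9)
  expect_equal(fc$mean_px, 7)
})

test_that("fit_sinusoid preconditions: span and sample count", {
  expect_error(fit_sinusoid(c(0, 10, 20), c(1, 2, 3)),
               class = "optomo_fit_error")
  expect_error(fit_sinusoid(seq(0, 150, by = 10), rnorm(16)),
               class = "optomo_fit_error")
})

test_that("noisy fit agrees with a grid-search-plus-refinement oracle", {
  set.seed(31)
  th <- (0:511) * 360 / 512
  truth <- c(A = 5, phi = -70, c = 40)
  v <- truth["A"] * cos((th + truth["phi"]) * pi / 180) + truth["c"] +
    rnorm(512, 0, 0.5)
  f <- fit_sinusoid(th, v)
  # oracle: coarse phase grid, linear solve for A and c at each phase,
  # golden-section refinement around the best grid point
  sse_at <- function(phi) {
    X <- cbind(cos((th + phi) * pi / 180), 1)
    sum(lm.fit(X, v)$residuals^2)
  }
  grid <- seq(-180, 179, by = 1)
  best <- grid[which.min(vapply(grid, sse_at, numeric(1)))]
  phi_o <- stats::optimize(sse_at, c(best - 2, best + 2))$minimum
  X <- cbind(cos((th + phi_o) * pi / 180), 1)
  beta <- lm.fit(X, v)$coefficients
  if (beta[1] < 0) {  # resolve the (A, phi) ~ (-A, phi + 180) ambiguity
    beta[1] <- -beta[1]
    phi_o <- phi_o + 180
  }
  phi_diff <- ((f$phase_deg - phi_o + 180) %% 360) - 180
  se <- 0.5 * sqrt(2 / 512)  # parameter standard error at sigma = 0.5
  expect_lt(abs(f$amplitude_px - beta[1]), 3 * se)
  expect_lt(abs(f$mean_px - beta[2]), 3 * se)
  expect_lt(abs(phi_diff) * pi / 180 * f$amplitude_px, 3 * se)
})

test_that("estimate_geometry recovers offset and tilt; degenerate amplitude", {
  fp <- sim_bead_scan(96, artifacts = artifact_spec(axis_offset_px = 5.25))
  tr <- track_fiducial(fp$stack, full_roi(fp$stack))
  m <- estimate_geometry(tr, detector_center_col(64))
  expect_lt(abs(m$axis_offset_px - 5.25), 0.25)
  expect_lt(abs(m$tilt_inplane_deg), 0.2)
  expect_lt(abs(m$tilt_outplane_deg), 0.2)
  fp2 <- sim_bead_scan(96, artifacts = artifact_spec(tilt_inplane_deg = 2),
                       size = c(24, 64, 64))
  tr2 <- track_fiducial(fp2$stack, full_roi(fp2$stack))
  m2 <- estimate_geometry(tr2, detector_center_col(64))
  expect_lt(abs(m2$tilt_inplane_deg - 2), 0.2)
  expect_lt(abs(m2$axis_offset_px), 0.25)
  # on-axis bead: amplitude ~ 0, tilts indeterminate but offset returned
  fp3 <- sim_bead_scan(96, bead_dy = 0, bead_dx = 0)
  tr3 <- track_fiducial(fp3$stack, full_roi(fp3$stack))
  m3 <- estimate_geometry(tr3, detector_center_col(64))
  expect_true(is.na(m3$tilt_inplane_deg))
  expect_lt(abs(m3$axis_offset_px), 0.25)
})

test_that("geometry recovery sweep stays within the stated error budget", {
  set.seed(17)
  cases <- data.frame(offset = runif(6, -8, 8), tilt = runif(6, -4, 4))
  for (i in seq_len(nrow(cases))) {
    fp <- sim_bead_scan(72, size = c(24, 64, 64), bead_dy = 6, bead_dx = 14,
                        artifacts = artifact_spec(
                          axis_offset_px = cases$offset[i],
                          tilt_inplane_deg = cases$tilt[i]))
    tr <- track_fiducial(fp$stack, full_roi(fp$stack))
    m <- estimate_geometry(tr, detector_center_col(64))
    expect_lt(abs(m$axis_offset_px - cases$offset[i]), 0.25)
    expect_lt(abs(m$tilt_inplane_deg - cases$tilt[i]), 0.3)
  }
})

test_that("dynamic_offset cancels injected jitter and is idempotent", {
  fp <- sim_bead_scan(128)
  clean_tr <- track_fiducial(fp$stack, full_roi(fp$stack))
  co0 <- dynamic_offset(clean_tr)
  expect_lt(max(abs(co0)), 0.3)  # zero-jitter corrections ~ 0
  jj <- inject_jitter(fp$stack, 2, 7)
  tr <- track_fiducial(jj$stack, full_roi(fp$stack))
  co <- dynamic_offset(tr)
  expect_lt(rmse(as.numeric(co), -jj$shifts), 0.5)
  # apply corrections, re-track, corrections should now be ~ 0
  data <- jj$stack$data
  for (i in seq_len(dim(data)[1]))
    data[i, , ] <- shift_image(matrix(jj$stack$data[i, , ], 16, 64), 0, co[i])
  fixed <- projection_stack(data, fp$stack$geometry)
  co2 <- dynamic_offset(track_fiducial(fixed, full_roi(fp$stack)))
  expect_lt(max(abs(co2)), 0.3)
})
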