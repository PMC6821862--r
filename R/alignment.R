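# Fiducial-based geometric calibration: track a bead through the projections,
# fit its ideal sinusoidal motion, estimate rotation-axis offset and tilt, and
# turn the fit residuals into per-angle jitter corrections.
#
# A bead at radius r from the axis traces x(theta) = c + A cos(theta + phi)
# across the detector. Axis tilt leaves signatures in the vertical motion:
# in-plane tilt alpha adds a component in phase with x (amplitude ratio
# tan(alpha)); out-of-plane tilt beta adds a quadrature component (ratio
# sin(beta)). Out-of-plane tilt mixes detector rows, which per-slice
# parallel-beam FBP cannot undo, so it is reported as a diagnostic only.

#' Detect a fiducial blob in one projection
#'
#' Thresholds the (optionally inverted) region of interest at
#' `mean + 3 sd` of its border pixels, picks the connected component nearest
#' `prev` (or the ROI center), and returns its intensity-weighted centroid
#' with sub-pixel precision.
#'
#' @param image (row, column) numeric matrix.
#' @param roi `c(row0, col0, height, width)` (0-based) or NULL for the whole
#'   image.
#' @param polarity `"bright"` (bead brighter than background) or `"dark"`.
#' @param prev previous bead position `c(x, y)` (0-based detector coords) used
#'   to disambiguate multiple blobs; NULL for the ROI center.
#' @return named numeric `c(x, y, npix)` (0-based column/row centroid and blob
#'   pixel count), or NULL when no blob exceeds the threshold.
#' @export
detect_fiducial <- function(image, roi = NULL, polarity = c("bright", "dark"),
                            prev = NULL) {
  polarity <- match.arg(polarity)
  d <- dim(image)
  if (is.null(roi)) roi <- c(0, 0, d[1], d[2])
  roi <- round(roi)
  if (roi[3] < 1 || roi[4] < 1) stop_value("empty roi")
  if (roi[1] < 0 || roi[2] < 0 || roi[1] + roi[3] > d[1] || roi[2] + roi[4] > d[2])
    stop_value("roi extends outside the image")
  win <- image[roi[1] + seq_len(roi[3]), roi[2] + seq_len(roi[4]), drop = FALSE]
  if (polarity == "dark") win <- max(win) - win
  nr <- nrow(win); nc <- ncol(win)
  border <- c(win[1, ], win[nr, ], win[, 1], win[, nc])
  thr <- mean(border) + 3 * stats::sd(border)
  if (!is.finite(thr)) thr <- mean(border)
  mask <- win > thr
  if (!any(mask)) return(NULL)
  # seed: above-threshold pixel nearest the previous hit / roi center
  tgt <- if (is.null(prev)) c((nr - 1) / 2, (nc - 1) / 2)
         else c(prev[2] - roi[1], prev[1] - roi[2])
  idx <- which(mask, arr.ind = TRUE)
  dist2 <- (idx[, 1] - 1 - tgt[1])^2 + (idx[, 2] - 1 - tgt[2])^2
  seed <- idx[which.min(dist2), ]
  # flood fill (4-connectivity) from the seed
  comp <- matrix(FALSE, nr, nc)
  comp[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -nc]
    grown[, -nc] <- grown[, -nc] | comp[, -1]
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  w <- (win - thr) * comp
  w[w < 0] <- 0
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  rows <- rep(seq_len(nr) - 1, times = nc)
  cols <- rep(seq_len(nc) - 1, each = nr)
  cy <- sum(rows * w) / tot + roi[1]
  cx <- sum(cols * w) / tot + roi[2]
  c(x = cx, y = cy, npix = sum(comp))
}

#' Track the fiducial bead through a projection stack
#'
#' Runs [detect_fiducial()] per projection with the search window re-centered
#' on the previous hit (window side = 3x the detected blob diameter). Gaps are
#' flagged `ok = FALSE`, never interpolated; more than 20% failures aborts
#' with per-angle diagnostics.
#'
#' @param stack a [projection_stack()].
#' @param seed_roi `c(row0, col0, height, width)` search region for the first
#'   projection.
#' @param polarity `"bright"` or `"dark"`.
#' @return a `fiducial_track`: data.frame with columns `angle_deg`, `x_px`,
#'   `y_px`, `ok`.
#' @export
track_fiducial <- function(stack, seed_roi = NULL, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(stack, "projection_stack"))
  d <- dim(stack$data)
  angles <- projection_angles(stack$geometry)
  n <- d[1]
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); ok <- logical(n)
  hit <- detect_fiducial(stack_plane(stack, 1), seed_roi, polarity)
  if (is.null(hit))
    stop_tracking("fiducial not found in the first projection's seed region")
  win_side <- max(9, ceiling(3 * 2 * sqrt(hit["npix"] / pi)))
  # the bead's ideal motion is horizontal; keep the search band no taller
  # than the seed region so it cannot drift into the sample's rows
  win_h <- if (is.null(seed_roi)) win_side else min(win_side, seed_roi[3])
  x[1] <- hit["x"]; y[1] <- hit["y"]; ok[1] <- TRUE
  last <- hit[c("x", "y")]
  for (i in 2:n) {
    r0 <- max(0, round(last[2] - win_h / 2))
    c0 <- max(0, round(last[1] - win_side / 2))
    h <- min(win_h, d[2] - r0); w <- min(win_side, d[3] - c0)
    hit <- detect_fiducial(stack_plane(stack, i), c(r0, c0, h, w), polarity,
                           prev = last)
    if (is.null(hit)) { ok[i] <- FALSE; next }
    x[i] <- hit["x"]; y[i] <- hit["y"]; ok[i] <- TRUE
    last <- hit[c("x", "y")]
  }
  track <- data.frame(angle_deg = angles, x_px = x, y_px = y, ok = ok)
  class(track) <- c("fiducial_track", "data.frame")
  if (mean(!ok) > 0.2)
    stop_tracking("fiducial lost in %d of %d projections (first misses: %s)",
                  sum(!ok), n, paste(utils::head(which(!ok), 5), collapse = ", "))
  track
}

#' Least-squares sinusoid fit of fiducial motion
#'
#' Fits `v(theta) = A cos(theta + phi) + c` through the linear
#' parameterization `a cos(theta) + b sin(theta) + c` (closed-form normal
#' equations), then `A = sqrt(a^2 + b^2)`, `phi = atan2(-b, a)`. Exact to
#' machine precision on noiseless sinusoids sampled at >= 4 distinct angles.
#'
#' @param angles_deg sample angles, degrees; must span more than 180 degrees.
#' @param values_px observed positions, px; NA entries are dropped.
#' @return a `sinusoid_fit`: list with `amplitude_px`, `phase_deg` (in
#'   [-180, 180)), `mean_px`, `a`, `b`, `fitted_px`, `residuals_px`
#'   (observed - fitted, NA where the observation was NA), `rmse_px`.
#' @export
fit_sinusoid <- function(angles_deg, values_px) {
  keep <- is.finite(values_px) & is.finite(angles_deg)
  if (sum(keep) < 4)
    stop_fit("need >= 4 usable samples, got %d", sum(keep))
  if (diff(range(angles_deg[keep])) <= 180)
    stop_fit("samples span %.1f deg; need > 180 deg", diff(range(angles_deg[keep])))
  th <- angles_deg * pi / 180
  X <- cbind(cos(th[keep]), sin(th[keep]), 1)
  beta <- solve(crossprod(X), crossprod(X, values_px[keep]))
  a <- beta[1]; b <- beta[2]; cc <- beta[3]
  fitted <- a * cos(th) + b * sin(th) + cc
  res <- values_px - fitted
  phase <- atan2(-b, a) * 180 / pi
  phase <- ((phase + 180) %% 360) - 180
  structure(list(amplitude_px = sqrt(a^2 + b^2), phase_deg = phase,
                 mean_px = cc, a = a, b = b, fitted_px = fitted,
                 residuals_px = res,
                 rmse_px = sqrt(mean(res[keep]^2))),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("<sinusoid_fit> A=%.3f px, phi=%.2f deg, c=%.3f px, rmse=%.3f px\n",
              x$amplitude_px, x$phase_deg, x$mean_px, x$rmse_px))
  invisible(x)
}

#' Rotation-axis geometry model
#'
#' @param axis_offset_px axis column minus detector center column, px.
#' @param tilt_inplane_deg in-plane axis tilt, degrees (|tilt| < 45).
#' @param tilt_outplane_deg out-of-plane axis tilt, degrees; diagnostic only
#'   (cannot be corrected by per-slice FBP). NA when indeterminate.
#' @param source `"estimated"` or `"user"`.
#' @return an object of class `geometry_model`.
#' @export
geometry_model <- function(axis_offset_px = 0, tilt_inplane_deg = 0,
                           tilt_outplane_deg = NA_real_,
                           source = c("user", "estimated")) {
  source <- match.arg(source)
  if (is.finite(tilt_inplane_deg) && abs(tilt_inplane_deg) >= 45)
    stop_value("in-plane tilt %.1f deg out of range (|tilt| < 45)", tilt_inplane_deg)
  structure(list(axis_offset_px = axis_offset_px,
                 tilt_inplane_deg = tilt_inplane_deg,
                 tilt_outplane_deg = tilt_outplane_deg,
                 source = source),
            class = "geometry_model")
}

#' @export
print.geometry_model <- function(x, ...) {
  cat(sprintf(
    "<geometry_model> offset=%.3f px, tilt in-plane=%s deg, out-of-plane=%s deg (%s)\n",
    x$axis_offset_px, format(x$tilt_inplane_deg, digits = 4),
    format(x$tilt_outplane_deg, digits = 4), x$source))
  invisible(x)
}

#' Estimate axis offset and tilt from a fiducial track
#'
#' The horizontal sinusoid fit gives the axis column (its mean), hence
#' `axis_offset_px = mean - detector_center_col`. The vertical motion is
#' decomposed against the horizontal phase: the component in phase with
#' `cos(theta + phi_x)` gives `tilt_inplane = atan(A_y_inphase / A_x)`; the
#' quadrature component gives the diagnostic
#' `tilt_outplane = asin(A_y_quad / A_x)`. When the horizontal amplitude is
#' below 1 px the tilts are indeterminate and returned as NA (the offset is
#' still returned).
#'
#' @param track a `fiducial_track` from [track_fiducial()].
#' @param detector_center_col detector center column, 0-based float
#'   `(n_columns - 1) / 2`.
#' @return a [geometry_model()] with `source = "estimated"`.
#' @export
estimate_geometry <- function(track, detector_center_col) {
  stopifnot(inherits(track, "fiducial_track"))
  fx <- fit_sinusoid(track$angle_deg, track$x_px)
  offset <- fx$mean_px - detector_center_col
  if (fx$amplitude_px < 1)
    return(geometry_model(offset, NA_real_, NA_real_, source = "estimated"))
  keep <- is.finite(track$y_px)
  phi <- atan2(-fx$b, fx$a)  # radians, exact (unnormalized) phase
  Phi <- track$angle_deg * pi / 180 + phi
  Y <- cbind(cos(Phi[keep]), sin(Phi[keep]), 1)
  beta <- solve(crossprod(Y), crossprod(Y, track$y_px[keep]))
  inphase <- beta[1]; quad <- beta[2]
  tilt_in <- atan2(inphase, fx$amplitude_px) * 180 / pi
  ratio <- max(-1, min(1, quad / fx$amplitude_px))
  tilt_out <- asin(ratio) * 180 / pi
  geometry_model(offset, tilt_in, tilt_out, source = "estimated")
}

#' Per-angle jitter corrections from a fiducial track
#'
#' Fits the ideal sinusoid to the bead's horizontal motion and returns, for
#' each angle, the additive column shift `-residual_i` that moves the
#' observed bead back onto the fit. Applying the corrections with
#' [create_sinograms()] cancels the per-angle jitter up to the bead
#' localization error. Angles where tracking failed get correction 0.
#'
#' @param track a `fiducial_track`.
#' @return numeric vector of per-angle correction shifts (px), with the
#'   underlying `sinusoid_fit` attached as attribute `"fit"`.
#' @export
dynamic_offset <- function(track) {
  stopifnot(inherits(track, "fiducial_track"))
  fx <- fit_sinusoid(track$angle_deg, track$x_px)
  corr <- -fx$residuals_px
  corr[!is.finite(corr)] <- 0
  attr(corr, "fit") <- fx
  corr
}
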