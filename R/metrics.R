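# Reconstruction quality metrics: Fourier ring correlation resolution from
# split-projection reconstructions, profile FWHM, and region SNR /
# brightness-ratio statistics.

#' Split a stack into interleaved half-stacks
#'
#' Even-indexed and odd-indexed angles (0-based interleave): each half spans
#' the full angular range with doubled step, so two independent
#' reconstructions of the same object can be compared (512 projections in,
#' two stacks of 256 out).
#'
#' @param stack a [projection_stack()] with an even number of projections.
#' @return list of two [projection_stack()]s, `a` (angles 0, 2, ...) and `b`
#'   (angles 1, 3, ...).
#' @export
split_projections <- function(stack) {
  stopifnot(inherits(stack, "projection_stack"))
  g <- stack$geometry
  n <- g$n_projections
  if (n %% 2 != 0) stop_value("cannot split an odd projection count (%d)", n)
  half <- function(first) {
    idx <- seq(first, n, by = 2)
    gg <- acquisition_geometry(
      n / 2, g$angular_range_deg,
      start_angle_deg = g$start_angle_deg +
        (first - 1) * g$angular_range_deg / n,
      pixel_size_um = g$pixel_size_um, min_step_deg = g$min_step_deg,
      modality = g$modality)
    projection_stack(stack$data[idx, , , drop = FALSE], gg, stage = stack$stage)
  }
  list(a = half(1), b = half(2))
}

# 2-d separable cosine-taper (Tukey) window with `margin` fraction per edge.
apodize_window <- function(nr, nc, margin = 0.1) {
  taper <- function(n) {
    m <- max(1, floor(margin * n))
    w <- rep(1, n)
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
    w
  }
  outer(taper(nr), taper(nc))
}

#' Fourier ring correlation between two images
#'
#' `FRC(r) = Re(sum_ring F1 conj(F2)) / sqrt(sum_ring |F1|^2 sum_ring |F2|^2)`
#' over centered rings of the 2-d DFTs. Resolution is `1 / f` at the first
#' crossing of the threshold (default 1/7), linearly interpolated between
#' rings; if the curve never crosses, `resolution_px` is NA and `reached` is
#' FALSE (never clamped). By default images are mean-subtracted and
#' edge-apodized (cosine taper, 10% margin) to suppress spectral leakage.
#'
#' @param img1,img2 equal-shape numeric matrices, at least 32 x 32.
#' @param ring_width ring width in cycles/px; default one frequency sample,
#'   `1 / min(dim)`.
#' @param threshold crossing criterion (default 1/7).
#' @param apodize apply the cosine edge taper (default TRUE).
#' @param mean_subtract subtract each image's mean first (default TRUE).
#' @param pixel_size_um optional pitch to report `resolution_um`.
#' @return an `frc_result`: list with `freq_cyc_per_px`, `frc`, `threshold`,
#'   `resolution_px`, `resolution_um`, `reached`.
#' @export
frc_curve <- function(img1, img2, ring_width = NULL, threshold = 1 / 7,
                      apodize = TRUE, mean_subtract = TRUE,
                      pixel_size_um = NA_real_) {
  if (!all(dim(img1) == dim(img2)))
    stop_geometry("image shapes differ: %s vs %s",
                  paste(dim(img1), collapse = "x"),
                  paste(dim(img2), collapse = "x"))
  if (any(dim(img1) < 32)) stop_value("images must be at least 32 x 32")
  nr <- nrow(img1); nc <- ncol(img1)
  if (mean_subtract) { img1 <- img1 - mean(img1); img2 <- img2 - mean(img2) }
  if (apodize) {
    w <- apodize_window(nr, nc)
    img1 <- img1 * w; img2 <- img2 * w
  }
  F1 <- stats::fft(img1); F2 <- stats::fft(img2)
  fr <- c(0:(nr %/% 2), seq.int(-((nr - 1) %/% 2), -1)) / nr
  fc <- c(0:(nc %/% 2), seq.int(-((nc - 1) %/% 2), -1)) / nc
  r <- sqrt(outer(fr^2, fc^2, `+`))
  if (is.null(ring_width)) ring_width <- 1 / min(nr, nc)
  ring <- as.integer(round(r / ring_width))
  n_rings <- as.integer(floor(0.5 / ring_width)) + 1L  # up to Nyquist
  keep <- ring < n_rings
  idx <- ring[keep] + 1L
  num <- Re(F1 * Conj(F2))[keep]
  p1 <- (Mod(F1)^2)[keep]
  p2 <- (Mod(F2)^2)[keep]
  s_num <- as.numeric(tapply(num, factor(idx, levels = seq_len(n_rings)), sum))
  s_p1 <- as.numeric(tapply(p1, factor(idx, levels = seq_len(n_rings)), sum))
  s_p2 <- as.numeric(tapply(p2, factor(idx, levels = seq_len(n_rings)), sum))
  den <- sqrt(s_p1 * s_p2)
  frc <- ifelse(is.na(den) | den == 0, NA_real_, s_num / den)
  freq <- (seq_len(n_rings) - 1) * ring_width
  # first downward threshold crossing, linearly interpolated
  res_px <- NA_real_; reached <- FALSE
  usable <- which(is.finite(frc))
  for (j in usable[usable > 1]) {
    jp <- max(usable[usable < j])
    if (length(jp) && is.finite(frc[jp]) && frc[jp] >= threshold && frc[j] < threshold) {
      f_cross <- freq[jp] + (threshold - frc[jp]) *
        (freq[j] - freq[jp]) / (frc[j] - frc[jp])
      res_px <- 1 / f_cross
      reached <- TRUE
      break
    }
  }
  structure(list(freq_cyc_per_px = freq, frc = frc, threshold = threshold,
                 resolution_px = res_px,
                 resolution_um = res_px * pixel_size_um,
                 reached = reached),
            class = "frc_result")
}

#' @export
print.frc_result <- function(x, ...) {
  res <- if (x$reached) sprintf("%.2f px", x$resolution_px) else "not reached"
  cat(sprintf("<frc_result> %d rings, threshold %.3f, resolution %s\n",
              length(x$frc), x$threshold, res))
  invisible(x)
}

#' FRC resolution from split-half reconstructions
#'
#' Splits the stack into interleaved halves, reconstructs both on the sampled
#' rows, computes the per-slice FRC, averages the curves, then thresholds the
#' average — the split-projection resolution estimate for a reconstructed
#' stack.
#'
#' @param stack a [projection_stack()] with even projection count.
#' @param geometry_model,jitter_corrections,filter passed to
#'   [reconstruct_volume()].
#' @param rows_sample 0-based rows to reconstruct and correlate.
#' @param pixel_size_um pitch for `resolution_um`; default from the stack
#'   geometry.
#' @param threshold FRC criterion (default 1/7).
#' @return an `frc_result` (curve averaged over the sampled rows).
#' @export
frc_resolution_from_halves <- function(stack, geometry_model = NULL,
                                       jitter_corrections = NULL,
                                       filter = filter_spec("ramp"),
                                       rows_sample = NULL,
                                       pixel_size_um = NULL,
                                       threshold = 1 / 7) {
  halves <- split_projections(stack)
  if (is.null(pixel_size_um)) pixel_size_um <- stack$geometry$pixel_size_um
  jc <- jitter_corrections
  jca <- if (is.null(jc)) NULL else jc[seq(1, length(jc), by = 2)]
  jcb <- if (is.null(jc)) NULL else jc[seq(2, length(jc), by = 2)]
  va <- reconstruct_volume(halves$a, geometry_model, jca, filter, rows_sample)
  vb <- reconstruct_volume(halves$b, geometry_model, jcb, filter, rows_sample)
  n_slices <- dim(va$voxels)[1]
  curves <- NULL
  template <- NULL
  for (k in seq_len(n_slices)) {
    f <- frc_curve(matrix(va$voxels[k, , ], dim(va$voxels)[2]),
                   matrix(vb$voxels[k, , ], dim(vb$voxels)[2]),
                   threshold = threshold)
    template <- f
    curves <- if (is.null(curves)) f$frc else curves + f$frc
  }
  avg <- curves / n_slices
  freq <- template$freq_cyc_per_px
  res_px <- NA_real_; reached <- FALSE
  for (j in 2:length(avg)) {
    if (is.finite(avg[j - 1]) && is.finite(avg[j]) &&
        avg[j - 1] >= threshold && avg[j] < threshold) {
      f_cross <- freq[j - 1] + (threshold - avg[j - 1]) *
        (freq[j] - freq[j - 1]) / (avg[j] - avg[j - 1])
      res_px <- 1 / f_cross; reached <- TRUE
      break
    }
  }
  structure(list(freq_cyc_per_px = freq, frc = avg, threshold = threshold,
                 resolution_px = res_px,
                 resolution_um = res_px * pixel_size_um,
                 reached = reached),
            class = "frc_result")
}

#' Full width at half maximum of an intensity profile
#'
#' Samples the image along a line with bilinear interpolation, subtracts the
#' baseline (minimum of the profile's two end thirds), and measures the
#' width between the sub-pixel half-maximum crossings bracketing the peak.
#'
#' @param image numeric matrix.
#' @param p0,p1 line endpoints, 0-based `c(row, col)`, inside the image.
#' @param step_px sampling step along the line (default 0.25 px).
#' @return width in pixels.
#' @export
profile_fwhm <- function(image, p0, p1, step_px = 0.25) {
  d <- dim(image)
  for (p in list(p0, p1))
    if (any(p < 0) || p[1] > d[1] - 1 || p[2] > d[2] - 1)
      stop_value("line endpoint outside the image")
  len <- sqrt(sum((p1 - p0)^2))
  t <- seq(0, 1, by = step_px / len)
  rows <- p0[1] + t * (p1[1] - p0[1])
  cols <- p0[2] + t * (p1[2] - p0[2])
  g <- bilinear_gather(rows, cols, d[1], d[2])
  v <- as.numeric(image)
  prof <- g[[1]]$w * v[g[[1]]$idx] + g[[2]]$w * v[g[[2]]$idx] +
          g[[3]]$w * v[g[[3]]$idx] + g[[4]]$w * v[g[[4]]$idx]
  n <- length(prof)
  third <- max(1, floor(n / 3))
  base <- min(c(prof[seq_len(third)], prof[seq(n - third + 1, n)]))
  prof <- prof - base
  pk <- which.max(prof)
  if (max(prof) <= 0 || max(prof) == min(prof))
    stop_value("flat profile: FWHM undefined")
  half <- prof[pk] / 2
  left <- NA_real_
  for (i in seq(pk, 2)) {
    if (prof[i - 1] < half && prof[i] >= half) {
      left <- (i - 1) + (half - prof[i - 1]) / (prof[i] - prof[i - 1]) - 1
      break
    }
  }
  right <- NA_real_
  for (i in seq(pk, n - 1)) {
    if (prof[i] >= half && prof[i + 1] < half) {
      right <- i + (prof[i] - half) / (prof[i] - prof[i + 1]) - 1
      break
    }
  }
  if (!is.finite(left) || !is.finite(right))
    stop_value("half-maximum crossings not found inside the profile")
  (right - left) * step_px
}

#' Region SNR and brightness-ratio statistics
#'
#' `snr = (mean_signal - mean_background) / sd_background` and
#' `br = mean_background / mean_signal`, the region statistics used to
#' compare labelling strategies.
#'
#' @param x numeric matrix or array.
#' @param signal_mask,background_mask logical masks of the same shape as `x`,
#'   non-empty and disjoint.
#' @return an `roi_stats` list: `mean_signal`, `mean_background`,
#'   `sd_background`, `snr`, `br`.
#' @export
roi_stats <- function(x, signal_mask, background_mask) {
  if (!any(signal_mask) || !any(background_mask))
    stop_value("masks must be non-empty")
  if (any(signal_mask & background_mask))
    stop_value("signal and background masks overlap")
  ms <- mean(x[signal_mask]); mb <- mean(x[background_mask])
  sb <- stats::sd(x[background_mask])
  if (!is.finite(sb) || sb == 0)
    stop_value("zero background SD: snr undefined")
  structure(list(mean_signal = ms, mean_background = mb, sd_background = sb,
                 snr = (ms - mb) / sb, br = mb / ms),
            class = "roi_stats")
}
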