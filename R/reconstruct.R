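# Sinogram assembly and filtered back-projection.
#
# Conventions: one sinogram per image row (the rotation axis is vertical);
# sinograms are (angle, detector column); after correction the axis sits at
# the detector center column (n_columns - 1) / 2. Angle sign: a point at
# slice offset (dy, dx) projects to detector coordinate
# s = dx cos(theta) - dy sin(theta) relative to the axis; the simulator and
# the back-projector share this constant and a round-trip test pins it.

#' One-slice sinogram
#'
#' @param data numeric matrix (angle, detector column).
#' @param angles_deg per-row projection angles, degrees.
#' @param center_col 0-based column of the rotation axis after corrections.
#' @param slice_row source image row (0-based), for provenance.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(data, angles_deg, center_col = detector_center_col(ncol(data)),
                     slice_row = NA_integer_) {
  data <- as.matrix(data)
  if (nrow(data) != length(angles_deg))
    stop_geometry("sinogram has %d rows but %d angles", nrow(data),
                  length(angles_deg))
  if (center_col < 0 || center_col > ncol(data) - 1)
    stop_value("center_col %.2f outside [0, %d]", center_col, ncol(data) - 1)
  structure(list(data = data, angles_deg = angles_deg, center_col = center_col,
                 slice_row = slice_row),
            class = "sinogram")
}

#' Frequency filter specification for FBP
#'
#' @param kind `"ramp"`, `"hamming"`, `"shepp_logan"` or `"none"`.
#' @param padding power-of-two zero-padding factor (>= 2): rows are padded to
#'   the next power of two >= `padding` x detector width before filtering, to
#'   suppress ramp-filter wrap-around.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("ramp", "hamming", "shepp_logan", "none"),
                        padding = 2) {
  kind <- match.arg(kind)
  if (padding < 2) stop_value("padding factor must be >= 2")
  structure(list(kind = kind, padding = padding), class = "filter_spec")
}

#' Assemble corrected sinograms from a projection stack
#'
#' Per angle: rotate the projection by `-tilt_inplane` about the image center
#' (bilinear), shift columns by `-axis_offset + jitter_correction_i` with
#' sub-pixel linear interpolation and zero fill, then extract each requested
#' row. After these corrections the rotation axis sits at the detector
#' center, so `center_col = (n_columns - 1) / 2`.
#'
#' `jitter_corrections` are additive column shifts as returned by
#' [dynamic_offset()] (already negated residuals).
#'
#' @param stack a [projection_stack()].
#' @param geometry_model a [geometry_model()] or NULL (identity).
#' @param jitter_corrections per-angle shifts (px) or NULL.
#' @param rows 0-based image rows to extract; NULL = all rows.
#' @return a list of [sinogram()] objects, one per requested row.
#' @export
create_sinograms <- function(stack, geometry_model = NULL,
                             jitter_corrections = NULL, rows = NULL) {
  stopifnot(inherits(stack, "projection_stack"))
  d <- dim(stack$data)
  n <- d[1]
  if (is.null(rows)) rows <- seq_len(d[2]) - 1
  if (any(rows < 0 | rows > d[2] - 1))
    stop_index("rows outside [0, %d]", d[2] - 1)
  if (!is.null(jitter_corrections) && length(jitter_corrections) != n)
    stop_geometry("%d jitter corrections for %d angles",
                  length(jitter_corrections), n)
  offset <- 0; tilt <- 0
  if (!is.null(geometry_model)) {
    offset <- geometry_model$axis_offset_px
    tilt <- geometry_model$tilt_inplane_deg
    if (!is.finite(tilt)) tilt <- 0
  }
  angles <- projection_angles(stack$geometry)
  sino_data <- array(0, dim = c(n, length(rows), d[3]))
  for (i in seq_len(n)) {
    p <- stack_plane(stack, i)
    if (tilt != 0) p <- rotate_image(p, -tilt)
    dc <- -offset + if (is.null(jitter_corrections)) 0 else jitter_corrections[i]
    if (dc != 0) p <- shift_image(p, 0, dc)
    sino_data[i, , ] <- p[rows + 1, , drop = FALSE]
  }
  cc <- detector_center_col(d[3])
  lapply(seq_along(rows), function(k)
    sinogram(matrix(sino_data[, k, ], n, d[3]), angles, cc, rows[k]))
}

#' Frequency response of an FBP filter
#'
#' Returns `H(f)` sampled at the discrete Fourier frequencies of an
#' `n_samples`-point transform with sample spacing `spacing`:
#' ramp `H = |f|` up to Nyquist; Shepp-Logan `|f| sinc(f / (2 f_N))`; Hamming
#' `|f| (0.54 + 0.46 cos(pi f / f_N))`; none = all-pass. The DC sample is set
#' to the discrete Ram-Lak value (the sum of the banded spatial-domain
#' kernel), not 0, to avoid a mean bias in the reconstruction.
#'
#' @param kind filter kind, as in [filter_spec()].
#' @param n_samples even padded row length.
#' @param spacing detector pixel pitch (units of length per sample).
#' @return numeric vector of length `n_samples` in FFT frequency order.
#' @export
design_filter <- function(kind = c("ramp", "hamming", "shepp_logan", "none"),
                          n_samples, spacing = 1) {
  kind <- match.arg(kind)
  if (n_samples %% 2 != 0) stop_value("n_samples must be even, got %d", n_samples)
  if (kind == "none") return(rep(1, n_samples))
  n <- n_samples
  k <- c(0:(n / 2), seq.int(-n / 2 + 1, -1))
  f <- k / (n * spacing)
  fN <- 1 / (2 * spacing)
  H <- abs(f)
  # DC from the discrete Ram-Lak spatial kernel: h(0) = 1/(4 s^2),
  # h(m) = -1/(pi^2 m^2 s^2) for odd m, 0 for even m (circularly arranged).
  dist <- pmin(0:(n - 1), n - (0:(n - 1)))
  h <- numeric(n)
  h[dist == 0] <- 1 / (4 * spacing^2)
  odd <- dist %% 2 == 1
  h[odd] <- -1 / (pi^2 * dist[odd]^2 * spacing^2)
  H[1] <- spacing * sum(h)
  w <- switch(kind,
    ramp = rep(1, n),
    shepp_logan = { x <- f / (2 * fN); ifelse(x == 0, 1, sin(pi * x) / (pi * x)) },
    hamming = 0.54 + 0.46 * cos(pi * f / fN))
  H * w
}

next_pow2 <- function(x) 2^ceiling(log2(x))

# Filter every sinogram row through H (built once) and return the filtered
# (angle, column) matrix, cropped back to the original width.
filter_sinogram <- function(data, filter) {
  n_ang <- nrow(data); w <- ncol(data)
  P <- next_pow2(filter$padding * w)
  H <- design_filter(filter$kind, P, spacing = 1)
  padded <- matrix(0, P, n_ang)
  padded[seq_len(w), ] <- t(data)
  ft <- stats::mvfft(padded) * H
  q <- Re(stats::mvfft(ft, inverse = TRUE)) / P
  t(q[seq_len(w), , drop = FALSE])
}

#' Filtered back-projection of one sinogram
#'
#' Each angle's row is zero-padded, frequency-filtered per [design_filter()],
#' and smeared back along its projection direction with linear interpolation.
#' The accumulation is scaled by `pi / n_angles` (the correct inversion
#' constant for `H = |f|`, for both 180 and 360 degree coverage — a full
#' revolution double-covers every direction). Pixels outside the inscribed
#' circle are set to 0.
#'
#' @param sino a [sinogram()].
#' @param filter a [filter_spec()].
#' @param output_size reconstruction side length in pixels (<= detector
#'   width); default = detector width.
#' @return an `output_size` x `output_size` matrix (row = y, col = x).
#' @export
fbp_slice <- function(sino, filter = filter_spec("ramp"), output_size = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  if (!nrow(sino$data) || !ncol(sino$data)) stop_value("empty sinogram")
  w <- ncol(sino$data)
  if (is.null(output_size)) output_size <- w
  if (output_size > w)
    stop_value("output_size %d exceeds detector width %d", output_size, w)
  q <- filter_sinogram(sino$data, filter)
  n_ang <- nrow(sino$data)
  scale <- pi / n_ang  # see note above; same constant for 180/360 coverage
  N <- output_size
  c0 <- (N - 1) / 2
  dy <- rep(seq_len(N) - 1 - c0, times = N)
  dx <- rep(seq_len(N) - 1 - c0, each = N)
  acc <- numeric(N * N)
  th <- sino$angles_deg * pi / 180
  for (i in seq_len(n_ang)) {
    s <- sino$center_col + dx * cos(th[i]) - dy * sin(th[i])
    acc <- acc + interp_row(q[i, ], s)
  }
  out <- matrix(acc * scale, N, N)
  out[dy^2 + dx^2 > c0^2 + 1e-9] <- 0
  out
}

#' Reconstructed voxel volume
#'
#' @param voxels numeric array (z, y, x).
#' @param voxel_size_um micrometers per voxel.
#' @param provenance list recording geometry/filter/corrections used.
#' @return an object of class `opt_volume`.
#' @export
opt_volume <- function(voxels, voxel_size_um = 1, provenance = list()) {
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um,
                 provenance = provenance),
            class = "opt_volume")
}

#' @export
print.opt_volume <- function(x, ...) {
  cat(sprintf("<opt_volume> %s voxels, %g um/voxel\n",
              paste(dim(x$voxels), collapse = " x "), x$voxel_size_um))
  invisible(x)
}

#' Reconstruct a volume slice-by-slice
#'
#' Assembles corrected sinograms for the requested rows and runs [fbp_slice()]
#' on each, independently; results are bit-identical regardless of the worker
#' count (no shared state, no RNG).
#'
#' @param stack a [projection_stack()].
#' @param geometry_model a [geometry_model()] or NULL.
#' @param jitter_corrections per-angle shifts or NULL.
#' @param filter a [filter_spec()].
#' @param rows 0-based image rows; NULL = all.
#' @param output_size slice side length, default detector width.
#' @param workers worker-process count for [parallel::mclapply()] (1 = serial).
#' @return an [opt_volume()] with one z-plane per requested row.
#' @export
reconstruct_volume <- function(stack, geometry_model = NULL,
                               jitter_corrections = NULL,
                               filter = filter_spec("ramp"), rows = NULL,
                               output_size = NULL, workers = 1L) {
  sinos <- create_sinograms(stack, geometry_model, jitter_corrections, rows)
  recon1 <- function(s) fbp_slice(s, filter, output_size)
  slices <- if (workers > 1)
    parallel::mclapply(sinos, recon1, mc.cores = workers)
  else lapply(sinos, recon1)
  N <- nrow(slices[[1]])
  vox <- array(0, dim = c(length(slices), N, N))
  for (k in seq_along(slices)) vox[k, , ] <- slices[[k]]
  opt_volume(vox, stack$geometry$pixel_size_um,
             provenance = list(
               geometry = stack$geometry, filter = filter,
               model = geometry_model,
               jitter_corrected = !is.null(jitter_corrections),
               rows = vapply(sinos, function(s) s$slice_row, numeric(1))))
}
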