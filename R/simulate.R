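# Forward simulator: parallel-beam (telecentric) projection of a phantom with
# controllable acquisition artifacts, so every calibration/correction routine
# in the package is testable by parameter recovery.

#' Acquisition artifact specification for the simulator
#'
#' @param axis_offset_px horizontal displacement of the rotation axis from the
#'   detector center column, sub-pixel, px.
#' @param tilt_inplane_deg rotation of the axis within the detector plane,
#'   degrees.
#' @param tilt_outplane_deg lean of the axis toward/away from the camera,
#'   degrees.
#' @param jitter_sigma_px standard deviation of per-angle horizontal jitter,
#'   px (rigid: the whole projection shifts together).
#' @param jitter_seed integer seed making the jitter reproducible.
#' @param illumination `NULL`, or a strictly positive (row, column) matrix
#'   multiplied onto every projection (see [illumination_field()]).
#' @param noise `"none"`, `"gaussian"` (additive, `noise_param` = sd in
#'   counts) or `"poisson"` (`noise_param` = mean photon count at unit
#'   intensity; values are scaled, Poisson-sampled, scaled back).
#' @param noise_param noise strength, see `noise`.
#' @param noise_seed integer seed for the noise draws.
#' @return an object of class `artifact_spec`.
#' @export
artifact_spec <- function(axis_offset_px = 0, tilt_inplane_deg = 0,
                          tilt_outplane_deg = 0, jitter_sigma_px = 0,
                          jitter_seed = 1L, illumination = NULL,
                          noise = c("none", "gaussian", "poisson"),
                          noise_param = 0, noise_seed = 1L) {
  noise <- match.arg(noise)
  if (jitter_sigma_px < 0) stop_value("jitter_sigma_px must be >= 0")
  if (!is.null(illumination) && any(illumination <= 0))
    stop_value("illumination field must be strictly positive")
  structure(list(axis_offset_px = axis_offset_px,
                 tilt_inplane_deg = tilt_inplane_deg,
                 tilt_outplane_deg = tilt_outplane_deg,
                 jitter_sigma_px = jitter_sigma_px,
                 jitter_seed = as.integer(jitter_seed),
                 illumination = illumination,
                 noise = noise, noise_param = noise_param,
                 noise_seed = as.integer(noise_seed)),
            class = "artifact_spec")
}

#' Smooth multiplicative illumination field
#'
#' A low-order polynomial bump emulating uneven collimation: value 1 at the
#' image center falling to `1 / peak_ratio` at the farthest edge.
#'
#' @param nrow,ncol field dimensions.
#' @param peak_ratio center-to-edge intensity ratio (default 1.5).
#' @return a strictly positive `(nrow, ncol)` matrix with max 1.
#' @export
illumination_field <- function(nrow, ncol, peak_ratio = 1.5) {
  cr <- (nrow - 1) / 2; cc <- (ncol - 1) / 2
  rr <- rep((seq_len(nrow) - 1 - cr) / max(cr, 1), times = ncol)
  cc2 <- rep((seq_len(ncol) - 1 - cc) / max(cc, 1), each = nrow)
  u2 <- (rr^2 + cc2^2) / 2  # 1 at the farthest corner
  matrix(1 - (1 - 1 / peak_ratio) * u2, nrow, ncol)
}

#' Parallel-beam forward projection of a phantom
#'
#' For each angle theta the phantom is rotated by `-theta` about the (possibly
#' offset and tilted) vertical rotation axis and integrated along the optical
#' axis; line integrals are in units of value x pixel. A point at offset
#' `(dy, dx)` from the axis appears at detector column
#' `center + A cos(theta + phi)` with `A cos(phi) = dx`, `A sin(phi) = dy`.
#' Artifacts are applied in physical order: out-of-plane then in-plane axis
#' tilt (as 3-d rotations of the object towards the camera frame), axis
#' offset (horizontal image shift), per-angle jitter, multiplicative
#' illumination, then noise.
#'
#' @param phantom an [make_phantom()] object.
#' @param geometry an [acquisition_geometry()].
#' @param artifacts an [artifact_spec()]; default: none.
#' @return a list with `stack` (a [projection_stack()], detector =
#'   `(nz rows, nx cols)`), and `jitter_shifts` (per-angle true shifts, px).
#' @export
forward_project <- function(phantom, geometry, artifacts = artifact_spec()) {
  stopifnot(inherits(phantom, "opt_phantom"))
  vox <- phantom$voxels
  d <- dim(vox)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (ny > nx)
    stop_geometry("phantom y extent (%d) exceeds detector width (%d)", ny, nx)
  if (ny < nx) {  # pad y symmetrically so rotation cannot clip the support
    pad_lo <- floor((nx - ny) / 2)
    v2 <- array(0, dim = c(nz, nx, nx))
    v2[, pad_lo + seq_len(ny), ] <- vox
    vox <- v2; ny <- nx
  }
  angles <- projection_angles(geometry)
  n <- geometry$n_projections
  a <- artifacts
  shifts <- if (a$jitter_sigma_px > 0)
    with_seed(a$jitter_seed, stats::rnorm(n, 0, a$jitter_sigma_px))
  else numeric(n)
  data <- array(0, dim = c(n, nz, nx))
  beta <- a$tilt_outplane_deg
  for (i in seq_len(n)) {
    v <- rotate_slices(vox, angles[i])
    if (beta != 0) {
      # lean the rotated object about the detector x-axis: warp (z, y) planes
      v <- aperm(rotate_slices(aperm(v, c(3, 1, 2)), beta), c(2, 3, 1))
    }
    proj <- colSums(aperm(v, c(2, 1, 3)))  # integrate along optical axis y
    if (a$tilt_inplane_deg != 0)
      proj <- rotate_image(proj, a$tilt_inplane_deg)
    dc <- a$axis_offset_px + shifts[i]
    if (dc != 0) proj <- shift_image(proj, 0, dc)
    data[i, , ] <- proj
  }
  if (!is.null(a$illumination)) {
    il <- a$illumination
    if (!all(dim(il) == c(nz, nx)))
      stop_geometry("illumination field is %s but projections are %d x %d",
                    paste(dim(il), collapse = " x "), nz, nx)
    for (i in seq_len(n)) data[i, , ] <- data[i, , ] * il
  }
  if (a$noise == "gaussian" && a$noise_param > 0) {
    data <- data + with_seed(a$noise_seed,
                             stats::rnorm(length(data), 0, a$noise_param))
  } else if (a$noise == "poisson" && a$noise_param > 0) {
    sc <- a$noise_param
    data <- with_seed(a$noise_seed,
                      array(stats::rpois(length(data), pmax(data, 0) * sc) / sc,
                            dim = dim(data)))
  }
  list(stack = projection_stack(data, geometry, stage = "raw"),
       jitter_shifts = shifts)
}

#' Inject per-angle horizontal jitter into a stack
#'
#' Each projection is rigidly shifted horizontally by an independent Gaussian
#' draw (seeded); the true shifts are returned for recovery tests.
#' `jitter_sigma_px = 0` is the identity.
#'
#' @param stack a [projection_stack()].
#' @param jitter_sigma_px jitter standard deviation, px (>= 0).
#' @param jitter_seed integer seed.
#' @return list with `stack` (shifted copy, `stage = "shifted"`) and `shifts`
#'   (numeric, one per angle).
#' @export
inject_jitter <- function(stack, jitter_sigma_px, jitter_seed = 1L) {
  stopifnot(inherits(stack, "projection_stack"))
  if (jitter_sigma_px < 0) stop_value("jitter_sigma_px must be >= 0")
  n <- stack$geometry$n_projections
  if (jitter_sigma_px == 0)
    return(list(stack = stack, shifts = numeric(n)))
  shifts <- with_seed(jitter_seed, stats::rnorm(n, 0, jitter_sigma_px))
  data <- stack$data
  for (i in seq_len(n))
    data[i, , ] <- shift_image(stack_plane(stack, i), 0, shifts[i])
  list(stack = projection_stack(data, stack$geometry, stage = "shifted"),
       shifts = shifts)
}

#' Convert an attenuation stack to simulated transmission counts
#'
#' Applies the Beer-Lambert law in the forward direction:
#' `I = I0 * exp(-A)`, for testing the correction round trip.
#'
#' @param stack a [projection_stack()] of line-integrated attenuation.
#' @param bright_level scalar or (row, col) matrix of bright-field counts I0.
#' @return a [projection_stack()] of intensities, `stage = "raw"`.
#' @export
attenuation_to_intensity <- function(stack, bright_level = 1000) {
  stopifnot(inherits(stack, "projection_stack"))
  data <- stack$data
  n <- dim(data)[1]
  if (is.matrix(bright_level)) {
    for (i in seq_len(n)) data[i, , ] <- bright_level * exp(-data[i, , ])
  } else {
    data <- bright_level * exp(-data)
  }
  projection_stack(data, stack$geometry, stage = "raw")
}
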