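#' Acquisition geometry of an OPT scan
#'
#' Describes the equiangular parallel-beam (telecentric) acquisition: how many
#' projections, over what angular range, at what object-space pixel pitch, and
#' in which modality (transmission `tOPT` or emission `eOPT`). The default
#' minimum angular step, 360/1024 = 0.35 degrees, corresponds to a stepper
#' motor with 1024 steps per revolution.
#'
#' @param n_projections number of projection angles (>= 2).
#' @param angular_range_deg degrees covered by the scan, in (0, 360].
#' @param start_angle_deg angle of the first projection, degrees.
#' @param pixel_size_um object-space pixel pitch in micrometers (camera pitch
#'   divided by magnification); must be > 0.
#' @param min_step_deg smallest realizable angular step of the rotation stage,
#'   degrees. Default 360/1024.
#' @param modality `"tOPT"` (transmission) or `"eOPT"` (emission).
#' @return an object of class `acquisition_geometry`.
#' @examples
#' g <- acquisition_geometry(512, pixel_size_um = 12.9)
#' head(projection_angles(g))
#' @export
acquisition_geometry <- function(n_projections,
                                 angular_range_deg = 360,
                                 start_angle_deg = 0,
                                 pixel_size_um = 1,
                                 min_step_deg = 360 / 1024,
                                 modality = c("tOPT", "eOPT")) {
  modality <- match.arg(modality)
  n_projections <- as.integer(n_projections)
  if (is.na(n_projections) || n_projections < 2)
    stop_value("n_projections must be an integer >= 2, got %s", n_projections)
  if (!(angular_range_deg > 0 && angular_range_deg <= 360))
    stop_value("angular_range_deg must lie in (0, 360], got %g", angular_range_deg)
  if (!(pixel_size_um > 0))
    stop_value("pixel_size_um must be > 0, got %g", pixel_size_um)
  structure(list(
    n_projections = n_projections,
    angular_range_deg = as.numeric(angular_range_deg),
    start_angle_deg = as.numeric(start_angle_deg),
    pixel_size_um = as.numeric(pixel_size_um),
    min_step_deg = as.numeric(min_step_deg),
    modality = modality
  ), class = "acquisition_geometry")
}

#' Projection angles of a scan
#'
#' Angle of projection `i` (0-based) is
#' `start_angle_deg + i * angular_range_deg / n_projections`; angles never
#' repeat within the stack (the end of the range is excluded).
#'
#' @param geometry an [acquisition_geometry()].
#' @return numeric vector of length `n_projections`, degrees.
#' @export
projection_angles <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  geometry$start_angle_deg +
    (seq_len(geometry$n_projections) - 1) *
      geometry$angular_range_deg / geometry$n_projections
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "<acquisition_geometry> %d projections over %g deg (step %.4g deg), %s, %g um/px\n",
    x$n_projections, x$angular_range_deg,
    x$angular_range_deg / x$n_projections, x$modality, x$pixel_size_um))
  invisible(x)
}

#' Angle-indexed projection stack
#'
#' Wraps a numeric array indexed `(angle, row, column)` with its acquisition
#' geometry and processing stage. All downstream operations (correction,
#' tracking, sinogram assembly, reconstruction) consume this container.
#'
#' @param data numeric array `(angle, row, column)`.
#' @param geometry an [acquisition_geometry()]; `n_projections` must equal
#'   `dim(data)[1]`.
#' @param stage processing stage: `"raw"`, `"flatfield_corrected"`,
#'   `"attenuation"` or `"shifted"`.
#' @return an object of class `projection_stack`.
#' @export
projection_stack <- function(data, geometry,
                             stage = c("raw", "flatfield_corrected",
                                       "attenuation", "shifted")) {
  stage <- match.arg(stage)
  stopifnot(inherits(geometry, "acquisition_geometry"))
  data <- as.array(data)
  if (length(dim(data)) != 3)
    stop_format("projection stack data must be a 3-d (angle, row, column) array")
  if (dim(data)[1] != geometry$n_projections)
    stop_geometry("stack has %d angle planes but geometry declares %d projections",
                  dim(data)[1], geometry$n_projections)
  storage.mode(data) <- "double"
  if (stage == "attenuation" && any(!is.finite(data)))
    stop_value("attenuation-stage stack contains non-finite values")
  structure(list(data = data, geometry = geometry, stage = stage),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<projection_stack> %d x (%d x %d), stage=%s, %s\n",
              d[1], d[2], d[3], x$stage, x$geometry$modality))
  invisible(x)
}

#' @export
dim.projection_stack <- function(x) dim(x$data)

# Extract projection i (1-based) as a matrix.
stack_plane <- function(stack, i) {
  d <- dim(stack$data)
  matrix(stack$data[i, , ], nrow = d[2], ncol = d[3])
}

#' Detector center column
#'
#' 0-based center of an `n_columns`-wide detector: `(n_columns - 1) / 2`, a
#' float so sub-pixel axis offsets are meaningful for even and odd widths.
#'
#' @param n_columns detector width in pixels.
#' @return numeric scalar.
#' @export
detector_center_col <- function(n_columns) (n_columns - 1) / 2
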