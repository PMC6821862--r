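# Stack I/O: multi-page TIFF plus a sidecar "key: value" manifest carrying the
# acquisition metadata (plain TIFF tags vary too much across dialects).

#' Write a key: value manifest
#'
#' One `key: value` pair per line; vectors are comma-separated. The manifest
#' travels next to a TIFF and carries geometry, stage and scaling metadata.
#'
#' @param x named list of scalars or vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    sprintf("%s: %s", k, paste(format(v, digits = 17, trim = TRUE,
                                      scientific = FALSE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a key: value manifest
#'
#' @param path manifest path.
#' @return named list of character vectors (split on commas); callers coerce.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io("manifest '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop_format("bad manifest line: '%s'", ln)
    out[[trimws(m[2])]] <- trimws(strsplit(m[3], ",")[[1]])
  }
  out
}

manifest_path <- function(path) paste0(path, ".manifest")

geometry_to_manifest <- function(geometry, stage = NULL, extra = list()) {
  m <- list(n_projections = geometry$n_projections,
            angular_range_deg = geometry$angular_range_deg,
            start_angle_deg = geometry$start_angle_deg,
            pixel_size_um = geometry$pixel_size_um,
            min_step_deg = geometry$min_step_deg,
            modality = geometry$modality)
  if (!is.null(stage)) m$stage <- stage
  c(m, extra)
}

geometry_from_manifest <- function(m) {
  acquisition_geometry(
    n_projections = as.integer(m$n_projections),
    angular_range_deg = as.numeric(m$angular_range_deg),
    start_angle_deg = as.numeric(m$start_angle_deg %||% 0),
    pixel_size_um = as.numeric(m$pixel_size_um %||% 1),
    min_step_deg = as.numeric(m$min_step_deg %||% (360 / 1024)),
    modality = as.character(m$modality %||% "tOPT"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a projection stack from TIFF
#'
#' Accepts a multi-page TIFF or a directory of single-page TIFFs in
#' lexicographic order (which defines angular order). Pixel values are
#' converted to double with the original dynamic range preserved — no
#' rescaling. If `geometry` is omitted a sidecar manifest (`<path>.manifest`
#' or `manifest.txt` inside a directory) must supply it.
#'
#' @param path TIFF file or directory of TIFFs.
#' @param geometry an [acquisition_geometry()]; page count must match
#'   `n_projections`.
#' @return a [projection_stack()] with `stage = "raw"` (or the stage recorded
#'   in the manifest).
#' @export
read_stack <- function(path, geometry = NULL) {
  stage <- "raw"
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop_io("no TIFF files in directory '%s'", path)
    mpath <- file.path(path, "manifest.txt")
    pages <- unlist(lapply(files, read_tiff), recursive = FALSE)
  } else {
    if (!file.exists(path)) stop_io("cannot read '%s': no such file", path)
    mpath <- manifest_path(path)
    pages <- read_tiff(path)
  }
  if (is.null(geometry)) {
    if (!file.exists(mpath))
      stop_config("no geometry given and no manifest at '%s'", mpath)
    m <- read_manifest(mpath)
    geometry <- geometry_from_manifest(m)
    stage <- as.character(m$stage %||% "raw")
  } else if (file.exists(mpath)) {
    stage <- as.character(read_manifest(mpath)$stage %||% "raw")
  }
  if (length(pages) != geometry$n_projections)
    stop_geometry("stack at '%s' has %d pages but geometry declares %d projections",
                  path, length(pages), geometry$n_projections)
  shapes <- unique(vapply(pages, function(p) paste(dim(p), collapse = "x"),
                          character(1)))
  if (length(shapes) != 1)
    stop_format("inconsistent page shapes in '%s': %s", path,
                paste(shapes, collapse = ", "))
  d <- dim(pages[[1]])
  data <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) data[i, , ] <- pages[[i]]
  # uint16-scaled stacks carry their affine scaling in the manifest
  if (file.exists(mpath)) {
    m <- read_manifest(mpath)
    if (!is.null(m$scale_min) && !is.null(m$scale_max)) {
      lo <- as.numeric(m$scale_min); hi <- as.numeric(m$scale_max)
      data <- data / 65535 * (hi - lo) + lo
    }
  }
  projection_stack(data, geometry, stage = stage)
}

#' Write a projection stack (or volume) to TIFF plus manifest
#'
#' `float32` round-trips bit-exactly; `uint16-scaled` maps the finite data
#' range onto 0..65535 and records `scale_min` / `scale_max` in the manifest
#' so [read_stack()] can undo the quantization (to within `(max-min)/65535`).
#'
#' @param stack a [projection_stack()] or an `opt_volume`.
#' @param path output TIFF path; the manifest is written to `<path>.manifest`.
#' @param dtype_policy `"float32"` or `"uint16-scaled"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype_policy = c("float32", "uint16-scaled")) {
  dtype_policy <- match.arg(dtype_policy)
  if (inherits(stack, "opt_volume")) {
    data <- stack$voxels
    manifest <- list(kind = "volume", voxel_size_um = stack$voxel_size_um)
  } else if (inherits(stack, "projection_stack")) {
    data <- stack$data
    manifest <- geometry_to_manifest(stack$geometry, stage = stack$stage)
  } else stop_value("write_stack expects a projection_stack or opt_volume")
  if (!dir.exists(dirname(path)))
    stop_io("parent directory '%s' does not exist", dirname(path))
  if (dtype_policy == "uint16-scaled") {
    if (any(!is.finite(data)))
      stop_value("non-finite values cannot be written under uint16-scaled policy")
    lo <- min(data); hi <- max(data)
    scaled <- if (hi > lo) (data - lo) / (hi - lo) * 65535 else data * 0
    write_tiff(path, scaled, dtype = "uint16")
    manifest$scale_min <- lo; manifest$scale_max <- hi
  } else {
    write_tiff(path, data, dtype = "float32")
  }
  write_manifest(manifest, manifest_path(path))
  invisible(path)
}
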