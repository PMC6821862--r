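# Projection correction: Beer-Lambert bright-field normalization for
# transmission data, flat/dark-field correction for emission data.

#' Average bright-field image
#'
#' @param image (row, column) matrix of bright-field counts I0.
#' @param n_averaged number of frames averaged into `image` (recorded only).
#' @return an object of class `bright_field`.
#' @export
bright_field <- function(image, n_averaged = 1L) {
  stopifnot(is.matrix(image))
  structure(list(image = image, n_averaged = as.integer(n_averaged)),
            class = "bright_field")
}

#' Beer-Lambert correction of transmission projections
#'
#' Divides each tOPT projection by the average bright-field image and takes
#' the negative log, per the Beer-Lambert law `I = I0 exp(-A)`:
#' `A = -ln( max(I, floor) / max(I0, floor) )`. Both numerator and
#' denominator are clamped below at `floor` so zeros cannot produce
#' infinities; negative attenuation (I > I0, i.e. noise) clamps to 0 by
#' default because unphysical negatives cause FBP streaks.
#'
#' @param stack a raw tOPT [projection_stack()].
#' @param bright a [bright_field()] (or bare matrix) matching the projection
#'   shape.
#' @param floor small positive intensity clamp, counts (default 1).
#' @param clamp_negative clamp A below at 0 (default TRUE); set FALSE to keep
#'   signed values.
#' @return a [projection_stack()] with `stage = "attenuation"`; all values
#'   finite and (by default) >= 0.
#' @export
beer_lambert_correct <- function(stack, bright, floor = 1, clamp_negative = TRUE) {
  stopifnot(inherits(stack, "projection_stack"))
  if (inherits(bright, "bright_field")) bright <- bright$image
  if (!(is.numeric(floor) && length(floor) == 1 && floor > 0))
    stop_value("floor must be a single positive intensity")
  d <- dim(stack$data)
  if (!all(dim(bright) == d[2:3]))
    stop_geometry("bright field is %s but projections are %d x %d",
                  paste(dim(bright), collapse = " x "), d[2], d[3])
  i0 <- pmax(bright, floor)
  data <- stack$data
  for (i in seq_len(d[1])) {
    a <- -log(pmax(stack_plane(stack, i), floor) / i0)
    if (clamp_negative) a <- pmax(a, 0)
    data[i, , ] <- a
  }
  projection_stack(data, stack$geometry, stage = "attenuation")
}

#' Dark/flat-field correction of emission projections
#'
#' `(I - dark) / normalized(flat)` per pixel, with the flat field normalized
#' to unit mean so overall intensity scale is preserved. Omitting both fields
#' is the identity.
#'
#' @param stack a raw eOPT [projection_stack()].
#' @param dark (row, column) dark-frame matrix or NULL.
#' @param flat (row, column) flat-field matrix or NULL.
#' @param floor relative clamp below which a normalized flat value is
#'   considered invalid (default 1e-6).
#' @return a [projection_stack()] with `stage = "flatfield_corrected"`.
#' @export
flatfield_correct <- function(stack, dark = NULL, flat = NULL, floor = 1e-6) {
  stopifnot(inherits(stack, "projection_stack"))
  d <- dim(stack$data)
  if (!is.null(dark) && !all(dim(dark) == d[2:3]))
    stop_geometry("dark frame shape mismatch")
  if (!is.null(flat)) {
    if (!all(dim(flat) == d[2:3])) stop_geometry("flat field shape mismatch")
    flat <- flat / mean(flat)
    if (any(flat <= floor))
      stop_value("flat field has non-positive values after normalization")
  }
  data <- stack$data
  for (i in seq_len(d[1])) {
    p <- stack_plane(stack, i)
    if (!is.null(dark)) p <- p - dark
    if (!is.null(flat)) p <- p / flat
    data[i, , ] <- p
  }
  projection_stack(data, stack$geometry, stage = "flatfield_corrected")
}
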