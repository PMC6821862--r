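# Shared fixtures: everything is generated in code at test time.

# Quantize doubles to float32 so float32 TIFF round trips can be exact.
float32 <- function(x) {
  v <- readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
               n = length(x), size = 4)
  if (!is.null(dim(x))) dim(v) <- dim(x)
  v
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Small bead-only scan: bead at (z, dy, dx) offset from the axis, optionally
# with acquisition artifacts. Returns forward_project()'s list.
sim_bead_scan <- function(n_angles = 128, size = c(16, 64, 64),
                          bead_dy = 8, bead_dx = 15, radius = 2,
                          artifacts = artifact_spec()) {
  ph <- make_phantom("bead", size,
                     center = c((size[1] - 1) / 2,
                                (size[2] - 1) / 2 + bead_dy,
                                (size[3] - 1) / 2 + bead_dx),
                     radius = radius)
  fp <- forward_project(ph, acquisition_geometry(n_angles), artifacts)
  fp$phantom <- ph
  fp
}

full_roi <- function(stack) c(0, 0, dim(stack$data)[2], dim(stack$data)[3])

# Independent oracle for the bead's detector trace: explicit 3-d rotation of
# the point coordinates with rotation matrices (no image warps). Conventions
# mirror the documented simulator geometry: rotate (dy, dx) by -theta about
# the axis, lean about the detector x-axis by beta, project along y, then
# rotate the detector plane by alpha and shift by the axis offset.
trace_point_oracle <- function(dz, dy, dx, angles_deg, alpha_deg = 0,
                               beta_deg = 0, offset_px = 0) {
  th <- angles_deg * pi / 180
  al <- alpha_deg * pi / 180
  be <- beta_deg * pi / 180
  y1 <- dy * cos(th) + dx * sin(th)
  x1 <- -dy * sin(th) + dx * cos(th)
  r1 <- dz * cos(be) + y1 * sin(be)
  row <- r1 * cos(al) + x1 * sin(al)
  col <- -r1 * sin(al) + x1 * cos(al) + offset_px
  list(row = row, col = col)
}
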