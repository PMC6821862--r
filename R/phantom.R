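# Test phantoms. Voxels are indexed (z, y, x) with the rotation axis along z.
# Values are attenuation coefficients (tOPT) or fluorophore density (eOPT).

#' Construct a 3-d phantom
#'
#' Deterministic synthetic objects used to exercise the forward model and the
#' reconstruction chain:
#' \describe{
#'   \item{`disks`}{a few uniform cylinders (circular disks replicated along
#'     z), with analytically known per-slice mass.}
#'   \item{`shepp_logan_3d`}{the classic head phantom replicated along z with
#'     a smooth z-envelope.}
#'   \item{`branching_tree`}{a coarse airway-tree caricature: a trunk cylinder
#'     that splits into two descending branches.}
#'   \item{`bead`}{a single Gaussian-profile sphere, emulating a small glass
#'     fiducial bead.}
#' }
#'
#' @param kind one of `"disks"`, `"shepp_logan_3d"`, `"branching_tree"`,
#'   `"bead"`.
#' @param size integer `c(z, y, x)`, each >= 8.
#' @param voxel_size_um micrometers per voxel.
#' @param ... shape parameters. `disks`: `disks` — a data.frame with columns
#'   `cy`, `cx` (0-based offsets from slice center, px), `r` (radius px),
#'   `value`. `bead`: `center` (0-based `c(z, y, x)`, defaults to the volume
#'   center), `radius` (Gaussian sigma-like radius, px, default 2), `value`
#'   (peak, default 1). `branching_tree`: `r_trunk` (default size/12).
#' @return an object of class `opt_phantom` with fields `voxels`,
#'   `voxel_size_um`.
#' @examples
#' ph <- make_phantom("bead", c(16, 32, 32), radius = 2)
#' @export
make_phantom <- function(kind, size, voxel_size_um = 1, ...) {
  if (length(size) != 3 || any(size < 8))
    stop_value("phantom size must be c(z, y, x) with all components >= 8")
  size <- as.integer(size)
  vox <- switch(kind,
    disks = phantom_disks(size, ...),
    shepp_logan_3d = phantom_sl3d(size, ...),
    branching_tree = phantom_tree(size, ...),
    bead = phantom_bead(size, ...),
    stop_value("unknown phantom kind '%s'", kind))
  structure(list(voxels = vox, voxel_size_um = voxel_size_um, kind = kind),
            class = "opt_phantom")
}

#' @export
print.opt_phantom <- function(x, ...) {
  cat(sprintf("<opt_phantom> kind=%s, %s voxels, %g um/voxel\n", x$kind,
              paste(dim(x$voxels), collapse = " x "), x$voxel_size_um))
  invisible(x)
}

default_disks <- function(size) {
  w <- min(size[2], size[3])
  data.frame(cy = c(0, -0.22, 0.2) * w,
             cx = c(0, 0.2, -0.18) * w,
             r = c(0.3, 0.1, 0.07) * w,
             value = c(0.5, 1, 0.8))
}

phantom_disks <- function(size, disks = default_disks(size), oversample = 4L) {
  nz <- size[1]; ny <- size[2]; nx <- size[3]
  os <- max(1L, as.integer(oversample))
  my <- ny * os; mx <- nx * os
  cy <- (my - 1) / 2; cx <- (mx - 1) / 2
  yy <- rep((seq_len(my) - 1 - cy) / os, times = mx)
  xx <- rep((seq_len(mx) - 1 - cx) / os, each = my)
  sl <- numeric(my * mx)
  for (i in seq_len(nrow(disks)))
    sl <- sl + disks$value[i] *
      ((yy - disks$cy[i])^2 + (xx - disks$cx[i])^2 <= disks$r[i]^2)
  if (os > 1L) {  # area-sampled edges: box-average os x os blocks
    dim(sl) <- c(os, ny, os, nx)
    sl <- apply(sl, c(2, 4), sum) / os^2
  }
  sl <- matrix(sl, ny, nx)
  vox <- array(0, dim = size)
  for (z in seq_len(nz)) vox[z, , ] <- sl
  vox
}

# Classic 10-ellipse head phantom on an n x n grid, values clipped to >= 0,
# coordinates in the usual [-1, 1]^2 convention (y up).
#' 2-d Shepp-Logan head phantom
#'
#' @param n side length in pixels.
#' @param modified use the high-contrast (modified) intensity set (default
#'   TRUE); values are clipped to be non-negative.
#' @param oversample sub-pixel supersampling factor for area-sampled
#'   rasterization of the ellipse boundaries (default 4; 1 = hard edges).
#'   Anti-aliased edges make the discrete image a faithful sample of the
#'   continuous object, which matters when comparing against band-limited
#'   reconstructions.
#' @return an `n x n` matrix (row = y down, col = x right).
#' @export
shepp_logan_phantom <- function(n, modified = TRUE, oversample = 4L) {
  # columns: intensity, a, b, x0, y0, phi_deg
  E <- matrix(c(
     1.0,   0.69,  0.92,  0.0,   0.0,     0,
    -0.8,   0.6624, 0.874, 0.0, -0.0184,  0,
    -0.2,   0.11,  0.31,  0.22,  0.0,   -18,
    -0.2,   0.16,  0.41, -0.22,  0.0,    18,
     0.1,   0.21,  0.25,  0.0,   0.35,    0,
     0.1,   0.046, 0.046, 0.0,   0.1,     0,
     0.1,   0.046, 0.046, 0.0,  -0.1,     0,
     0.1,   0.046, 0.023, -0.08, -0.605,  0,
     0.1,   0.023, 0.023,  0.0,  -0.606,  0,
     0.1,   0.023, 0.046,  0.06, -0.605,  0), ncol = 6, byrow = TRUE)
  if (modified) E[, 1] <- c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  os <- max(1L, as.integer(oversample))
  m <- n * os
  c0 <- (m - 1) / 2
  x <- rep((seq_len(m) - 1 - c0) / (n / 2 * os), each = m)   # col -> x right
  y <- rep(-(seq_len(m) - 1 - c0) / (n / 2 * os), times = m) # row -> y up
  img <- numeric(m * m)
  for (i in seq_len(nrow(E))) {
    a <- E[i, 2]; b <- E[i, 3]
    xr <- x - E[i, 4]; yr <- y - E[i, 5]
    phi <- E[i, 6] * pi / 180
    u <- xr * cos(phi) + yr * sin(phi)
    v <- -xr * sin(phi) + yr * cos(phi)
    img <- img + E[i, 1] * ((u / a)^2 + (v / b)^2 <= 1)
  }
  img <- matrix(pmax(img, 0), nrow = m)
  if (os == 1L) return(img)
  # box-average os x os blocks back to n x n
  dim(img) <- c(os, n, os, n)
  out <- apply(img, c(2, 4), sum) / os^2
  matrix(out, n, n)
}

phantom_sl3d <- function(size) {
  nz <- size[1]
  sl <- shepp_logan_phantom(min(size[2], size[3]))
  base <- matrix(0, size[2], size[3])
  base[seq_len(nrow(sl)), seq_len(ncol(sl))] <- sl
  env <- sin(pi * (seq_len(nz) - 0.5) / nz)  # smooth z-envelope
  vox <- array(0, dim = size)
  for (z in seq_len(nz)) vox[z, , ] <- env[z] * base
  vox
}

phantom_tree <- function(size, r_trunk = max(2, min(size[2:3]) / 12)) {
  nz <- size[1]; ny <- size[2]; nx <- size[3]
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  yy <- rep(seq_len(ny) - 1 - cy, times = nx)
  xx <- rep(seq_len(nx) - 1 - cx, each = ny)
  vox <- array(0, dim = size)
  split_z <- nz / 2
  for (z in seq_len(nz)) {
    sl <- numeric(ny * nx)
    if (z <= split_z) {
      sl <- sl + ((yy)^2 + (xx)^2 <= r_trunk^2)
    } else {
      # two branches drifting apart with depth, thinning as they go
      t <- (z - split_z) / (nz - split_z)
      dx <- t * min(ny, nx) / 5
      rb <- r_trunk * (1 - 0.4 * t)
      sl <- sl + ((yy)^2 + (xx - dx)^2 <= rb^2) + ((yy)^2 + (xx + dx)^2 <= rb^2)
    }
    vox[z, , ] <- pmin(sl, 1)
  }
  vox
}

phantom_bead <- function(size, center = (size - 1) / 2, radius = 2, value = 1) {
  nz <- size[1]; ny <- size[2]; nx <- size[3]
  zz <- seq_len(nz) - 1 - center[1]
  yy <- seq_len(ny) - 1 - center[2]
  xx <- seq_len(nx) - 1 - center[3]
  gz <- exp(-zz^2 / (2 * radius^2))
  gy <- exp(-yy^2 / (2 * radius^2))
  gx <- exp(-xx^2 / (2 * radius^2))
  vox <- value * outer(outer(gz, gy), gx)
  dim(vox) <- c(nz, ny, nx)
  vox
}
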