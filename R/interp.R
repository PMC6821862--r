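# Bilinear warps shared by the simulator, sinogram assembly and FBP.
#
# Coordinate convention (package-wide): 0-based continuous coordinates with
# pixel centers at integers; (row 0, col 0) is the top-left pixel; the center
# of an n-pixel axis is (n - 1) / 2 (a float, symmetric for even and odd n).
# Samples outside the grid contribute 0.

# Precompute bilinear gather indices/weights for sampling an (nr x nc) plane
# at continuous 0-based (src_row, src_col). Returns 1-based linear plane
# indices (column-major) with out-of-range weights zeroed.
bilinear_gather <- function(src_row, src_col, nr, nc) {
  r0 <- floor(src_row); c0 <- floor(src_col)
  fr <- src_row - r0;   fc <- src_col - c0
  out <- vector("list", 4L)
  k <- 1L
  for (a in 0:1) {
    wa <- if (a == 0) 1 - fr else fr
    rr <- r0 + a
    for (b in 0:1) {
      wb <- if (b == 0) 1 - fc else fc
      cc <- c0 + b
      ok <- rr >= 0 & rr < nr & cc >= 0 & cc < nc
      w <- wa * wb
      w[!ok] <- 0
      idx <- rr + nr * cc + 1
      idx[!ok] <- 1L
      out[[k]] <- list(idx = idx, w = w)
      k <- k + 1L
    }
  }
  out
}

# Sample one matrix through a precomputed gather.
apply_gather_matrix <- function(img, g, out_dim) {
  v <- as.numeric(img)
  acc <- g[[1]]$w * v[g[[1]]$idx]
  for (k in 2:4) acc <- acc + g[[k]]$w * v[g[[k]]$idx]
  matrix(acc, nrow = out_dim[1], ncol = out_dim[2])
}

# Sample every slice of an (n, nr, nc) array through the same gather.
# Slices live along dim 1; returns (n, out_nr, out_nc).
apply_gather_slices <- function(vol, g, out_dim) {
  n <- dim(vol)[1]
  m <- matrix(vol, nrow = n)  # n x (nr*nc), plane indices column-major
  acc <- m[, g[[1]]$idx, drop = FALSE] * rep(g[[1]]$w, each = n)
  for (k in 2:4)
    acc <- acc + m[, g[[k]]$idx, drop = FALSE] * rep(g[[k]]$w, each = n)
  array(acc, dim = c(n, out_dim[1], out_dim[2]))
}

# Source coordinates for rotating plane content by `angle_deg` about `center`
# (0-based c(row, col)). Output pixel u maps to source R(angle) %*% u, with
# R = [[cos, -sin], [sin, cos]] acting on (row, col) offsets: a point at
# offset (dr, dc) appears at output offset R(-angle) %*% (dr, dc).
rotation_coords <- function(nr, nc, angle_deg, center = NULL) {
  if (is.null(center)) center <- c((nr - 1) / 2, (nc - 1) / 2)
  th <- angle_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  dr <- rep(seq_len(nr) - 1 - center[1], times = nc)
  dc <- rep(seq_len(nc) - 1 - center[2], each = nr)
  list(row = center[1] + cs * dr - sn * dc,
       col = center[2] + sn * dr + cs * dc)
}

#' Rotate an image about a point with bilinear interpolation
#'
#' Rotates image content counter-clockwise in (row, col) index space by
#' `angle_deg`; areas swept in from outside the grid are zero-filled.
#'
#' @param img numeric matrix.
#' @param angle_deg rotation angle in degrees.
#' @param center 0-based `c(row, col)` pivot; default is the image center
#'   `((nr-1)/2, (nc-1)/2)`.
#' @return a matrix of the same dimensions.
#' @export
rotate_image <- function(img, angle_deg, center = NULL) {
  if (angle_deg == 0) return(img)
  d <- dim(img)
  co <- rotation_coords(d[1], d[2], angle_deg, center)
  g <- bilinear_gather(co$row, co$col, d[1], d[2])
  apply_gather_matrix(img, g, d)
}

# Rotate the (dim2, dim3) plane of every dim-1 slice by the same angle.
rotate_slices <- function(vol, angle_deg, center = NULL) {
  d <- dim(vol)
  if (angle_deg == 0) return(vol)
  co <- rotation_coords(d[2], d[3], angle_deg, center)
  g <- bilinear_gather(co$row, co$col, d[2], d[3])
  apply_gather_slices(vol, g, d[2:3])
}

#' Translate an image by a sub-pixel shift
#'
#' Content moves by `(dr, dc)` pixels (positive = down / right); vacated
#' regions are zero-filled; linear interpolation for fractional shifts.
#'
#' @param img numeric matrix.
#' @param dr,dc row / column shift in pixels.
#' @return a matrix of the same dimensions.
#' @export
shift_image <- function(img, dr = 0, dc = 0) {
  if (dr == 0 && dc == 0) return(img)
  d <- dim(img)
  src_r <- rep(seq_len(d[1]) - 1 - dr, times = d[2])
  src_c <- rep(seq_len(d[2]) - 1 - dc, each = d[1])
  g <- bilinear_gather(src_r, src_c, d[1], d[2])
  apply_gather_matrix(img, g, d)
}

# Linear interpolation of a sampled row q (0-based positions 0..n-1) at
# continuous positions s; zero outside.
interp_row <- function(q, s) {
  n <- length(q)
  i0 <- floor(s)
  f <- s - i0
  ok0 <- i0 >= 0 & i0 <= n - 1
  ok1 <- i0 + 1 >= 0 & i0 + 1 <= n - 1
  a <- numeric(length(s)); b <- numeric(length(s))
  a[ok0] <- q[i0[ok0] + 1]
  b[ok1] <- q[i0[ok1] + 2]
  (1 - f) * a + f * b
}
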