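# Shared low-level array helpers: trilinear / nearest-neighbour sampling,
# separable Gaussian smoothing, in-plane resizing, axis shifts.
# All grids follow the package convention: dim = (nx, ny, nx is fastest);
# slice z is the contiguous plane arr[, , z].

#' @keywords internal
#' @noRd
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based). Coordinates outside the grid return `fill`.
#' @noRd
interp3_linear <- function(arr, xi, yi, zi, fill = 0) {
  interp3_linear_cpp(arr, dim(arr), as.numeric(xi), as.numeric(yi),
                     as.numeric(zi), fill)
}

# Nearest-neighbour interpolation; used for label maps so values stay binary.
#' @noRd
interp3_nearest <- function(arr, xi, yi, zi, fill = 0) {
  d <- dim(arr)
  xi <- round(xi); yi <- round(yi); zi <- round(zi)
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(fill, length(xi))
  if (any(inside)) {
    out[inside] <- arr[((zi[inside] - 1) * d[2] + (yi[inside] - 1)) * d[1] +
                         xi[inside]]
  }
  out
}

# Gradient of a 3D array by central differences, per physical mm.
# Returns a list of three arrays (d/dx, d/dy, d/dz).
#' @noRd
gradient3 <- function(arr, spacing) {
  d <- dim(arr)
  g <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] < 2) { g[[ax]] <- array(0, d); next }
    up <- shift_axis(arr, ax, 1L)
    dn <- shift_axis(arr, ax, -1L)
    g[[ax]] <- (up - dn) / (2 * spacing[ax])
  }
  g
}

# Shift an array by `by` voxels along `axis` with edge replication.
#' @noRd
shift_axis <- function(arr, axis, by) {
  d <- dim(arr)
  idx <- .clamp(seq_len(d[axis]) + by, 1, d[axis])
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Separable Gaussian smoothing with per-axis sigma in voxels.
#' @noRd
gauss_smooth3 <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0 || dim(arr)[ax] < 2) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim(arr))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_axis(arr, ax, j - r - 1L)
    }
    arr <- acc
  }
  arr
}

# Downsample an array by integer factor f per axis (Gaussian anti-alias then
# strided subsampling). Returns the array; caller rescales spacing.
#' @noRd
downsample3 <- function(arr, f) {
  if (f == 1) return(arr)
  arr <- gauss_smooth3(arr, rep(f / 2, 3))
  d <- dim(arr)
  arr[seq(1, d[1], by = f), seq(1, d[2], by = f), seq(1, d[3], by = f),
      drop = FALSE]
}

# Resize a 2D matrix to nh x nw. mode "bilinear" for images, "nearest"
# for labels (closure over {0,1} guaranteed).
#' @noRd
resize2 <- function(mat, nh, nw, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(mat)
  # align centres: map output pixel centre to input pixel centre
  xs <- (seq_len(nh) - 0.5) * d[1] / nh + 0.5
  ys <- (seq_len(nw) - 0.5) * d[2] / nw + 0.5
  xi <- rep(xs, times = nw)
  yi <- rep(ys, each = nh)
  a3 <- array(mat, c(d[1], d[2], 1))
  v <- if (mode == "bilinear") {
    interp3_linear(a3, .clamp(xi, 1, d[1]), .clamp(yi, 1, d[2]),
                   rep(1, length(xi)))
  } else {
    interp3_nearest(a3, .clamp(xi, 1, d[1]), .clamp(yi, 1, d[2]),
                    rep(1, length(xi)))
  }
  matrix(v, nh, nw)
}
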