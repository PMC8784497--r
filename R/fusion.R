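# The combined-approach (COM) operator: dilate the multi-atlas mask
# in-plane, then intersect voxel-wise with the adversarial network's mask.
# The dilated atlas mask acts as a spatial gate that removes the network's
# distant false-positive blobs while the network recovers precise borders.

#' Morphological dilation of a binary mask
#'
#' In-plane (per-slice) dilation: a 3x3 4-connected cross applied
#' `radius_px` times, i.e. a city-block ball of the given radius. Dilation
#' is 2D rather than 3D because slice spacing (~5 mm) is far coarser than
#' the in-plane resolution, so an isotropic 3D element would be
#' anisotropically wrong; set `in_plane = FALSE` to dilate across slices
#' too.
#'
#' @param mask A [binary_mask()].
#' @param radius_px Non-negative integer radius in pixels; 0 is the
#'   identity.
#' @param in_plane If `TRUE` (default) dilate within each axial slice only.
#' @return A [binary_mask()] containing the input.
#' @export
dilate_mask <- function(mask, radius_px = 2, in_plane = TRUE) {
  stopifnot(inherits(mask, "binary_mask"))
  radius_px <- as.integer(radius_px)
  if (is.na(radius_px) || radius_px < 0)
    stop("radius_px must be a non-negative integer", call. = FALSE)
  v <- mask$voxels
  if (radius_px > 0) {
    for (i in seq_len(radius_px)) {
      out <- v |
        shift_mask(v, 1, 1L) | shift_mask(v, 1, -1L) |
        shift_mask(v, 2, 1L) | shift_mask(v, 2, -1L)
      if (!in_plane)
        out <- out | shift_mask(v, 3, 1L) | shift_mask(v, 3, -1L)
      v <- out
    }
  }
  binary_mask(v, spacing = mask$spacing, case_id = mask$case_id,
              label = mask$label)
}

# shift a logical array by one voxel along an axis, padding with FALSE
#' @noRd
shift_mask <- function(v, axis, by) {
  d <- dim(v)
  out <- array(FALSE, d)
  n <- d[axis]
  src <- if (by > 0) 1:(n - 1) else 2:n
  dst <- if (by > 0) 2:n else 1:(n - 1)
  switch(axis,
         out[dst, , ] <- v[src, , ],
         out[, dst, ] <- v[, src, ],
         out[, , dst] <- v[, , src])
  out
}

#' Combine multi-atlas and network masks
#'
#' The hybrid mask: the multi-atlas mask is dilated by `radius_px` pixels
#' (see [dilate_mask()]) and intersected voxel-wise (AND) with the network
#' mask — a voxel is muscle only if both methods agree. The result is
#' always a subset of the network mask and of the dilated atlas mask.
#'
#' @param mas_mask Multi-atlas segmentation [binary_mask()].
#' @param gan_mask Network segmentation [binary_mask()] on the same grid.
#' @param radius_px Dilation radius in pixels (default 2).
#' @param in_plane Passed to [dilate_mask()].
#' @return A [binary_mask()].
#' @export
combine_masks <- function(mas_mask, gan_mask, radius_px = 2, in_plane = TRUE) {
  stopifnot(inherits(mas_mask, "binary_mask"),
            inherits(gan_mask, "binary_mask"))
  stop_if_grid_mismatch(mas_mask, gan_mask, "mas/gan masks")
  dil <- dilate_mask(mas_mask, radius_px, in_plane = in_plane)
  binary_mask(dil$voxels & gan_mask$voxels, spacing = gan_mask$spacing,
              case_id = gan_mask$case_id, label = gan_mask$label)
}
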