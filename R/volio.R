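# Data model for CT volumes and binary masks, plus NIfTI readers/writers.
#
# Grid convention: arrays have dim (nx, ny, nz); the x index is fastest and
# arr[, , z] is the contiguous axial slice plane, matching RNifti.

#' Construct an image volume
#'
#' An `image_volume` holds a 3D grid of CT intensities in Hounsfield units
#' together with its voxel spacing and origin in millimetres. The pipeline
#' requires at least 3 slices (the 2.5D segmenter stacks each slice with its
#' two axial neighbours).
#'
#' @param voxels Numeric 3D array, dim `(nx, ny, nz)`; `[, , z]` is slice `z`.
#' @param spacing Numeric length-3 `(sx, sy, sz)` voxel spacing in mm; all
#'   components must be positive.
#' @param origin Numeric length-3 physical origin in mm.
#' @param case_id Opaque case identifier.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0), case_id = "") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)", call. = FALSE)
  if (dim(voxels)[3] < 3L)
    stop("volume must have at least 3 slices (2.5D stacking needs both axial neighbours)",
         call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), case_id = as.character(case_id)),
            class = "image_volume")
}

#' Construct a binary mask
#'
#' A `binary_mask` is a boolean grid aligned with an [image_volume()] grid.
#' The `label` records whether it marks the left psoas, the right psoas, or
#' their bilateral union (the quantity evaluated throughout).
#'
#' @param voxels Logical (or coercible) 3D array on the paired volume's grid.
#' @param spacing Voxel spacing `(sx, sy, sz)` in mm.
#' @param case_id Case identifier.
#' @param label One of `"left_psoas"`, `"right_psoas"`, `"bilateral"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, case_id = "",
                        label = c("bilateral", "left_psoas", "right_psoas")) {
  label <- match.arg(label)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  storage.mode(voxels) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing,
                 case_id = as.character(case_id), label = label),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_volume '%s': %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              x$case_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary_mask '%s' (%s): %d x %d x %d, %d foreground voxels\n",
              x$case_id, x$label, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' @noRd
stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(dim(a$voxels), collapse = "x"),
                 paste(dim(b$voxels), collapse = "x")), call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-4)
    stop(sprintf("%s have different voxel spacing", what), call. = FALSE)
  invisible(NULL)
}

#' Read a CT volume from NIfTI
#'
#' Reads a NIfTI-1 `.nii`/`.nii.gz` file into an [image_volume()]. Voxel
#' spacing is taken from the file header; a header without usable pixel
#' dimensions is an error — spacing is never silently assumed to be 1 mm.
#' DICOM series directories are not supported; convert to NIfTI first.
#'
#' @param path Path to a NIfTI file.
#' @param case_id Case identifier; defaults to the file name stem.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, case_id = NULL) {
  if (dir.exists(path))
    stop(sprintf("'%s' is a directory; DICOM series input is not supported, convert the series to NIfTI", path),
         call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("cannot read volume: no such file '%s'", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read volume '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop(sprintf("volume '%s' has no usable voxel spacing in its header; refusing to assume 1 mm",
                 path), call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  image_volume(unclass(img)[, , , drop = FALSE], spacing = sp[1:3],
               origin = org, case_id = case_id)
}

#' Write a CT volume to NIfTI
#'
#' @param volume An [image_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  vox <- volume$voxels
  attr(vox, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(vox, datatype = "float")
  img <- RNifti::asNifti(img, list(qform_code = 1,
                                   qoffset_x = volume$origin[1],
                                   qoffset_y = volume$origin[2],
                                   qoffset_z = volume$origin[3]))
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop(sprintf("cannot write volume to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Any nonzero voxel maps to `TRUE` (the common dialect across segmentation
#' tools, which variously store masks as 0/1, 0/255 or float).
#'
#' @param path Path to a NIfTI mask file.
#' @param case_id Case identifier; defaults to the file name stem.
#' @param label Mask label, see [binary_mask()].
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, case_id = NULL, label = "bilateral") {
  if (!file.exists(path) || dir.exists(path))
    stop(sprintf("cannot read mask: no such file '%s'", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read mask '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop(sprintf("mask '%s' has no usable voxel spacing in its header", path),
         call. = FALSE)
  if (is.null(case_id))
    case_id <- sub("(_mask)?\\.nii(\\.gz)?$", "", basename(path))
  binary_mask(unclass(img)[, , , drop = FALSE] != 0, spacing = sp[1:3],
              case_id = case_id, label = label)
}

#' Write a binary mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit 0/1 volumes so every voxel survives a
#' write-read round trip exactly.
#'
#' @param mask A [binary_mask()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  vox <- array(as.integer(mask$voxels), dim(mask$voxels))
  attr(vox, "pixdim") <- mask$spacing
  img <- RNifti::asNifti(vox, datatype = "uint8")
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop(sprintf("cannot write mask to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Merge left and right psoas masks into a bilateral mask
#'
#' Voxel-wise OR of the two single-muscle masks. The bilateral mask is the
#' quantity all volumetry and overlap statistics are reported on.
#'
#' @param left,right [binary_mask()] objects on the same grid.
#' @return A [binary_mask()] with `label = "bilateral"`.
#' @export
merge_lr <- function(left, right) {
  stopifnot(inherits(left, "binary_mask"), inherits(right, "binary_mask"))
  stop_if_grid_mismatch(left, right, "left/right masks")
  binary_mask(left$voxels | right$voxels, spacing = left$spacing,
              case_id = left$case_id, label = "bilateral")
}
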