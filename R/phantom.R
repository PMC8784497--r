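# Synthetic abdominal-CT phantom cohort: a fat-density body ellipse with a
# bone column and two tapering paraspinal muscle tubes, deformed per case by
# a smooth random displacement field. Stands in for a clinical CT cohort in
# every test and desk experiment.

#' Phantom generator parameters
#'
#' Defaults describe the desk-scale phantom: a 64 x 64 x 24 grid at
#' (2, 2, 5) mm — 5 mm slice thickness matching routine abdominal CT, with
#' the in-plane matrix scaled down from the clinical 512 x 512. Tissue
#' intensities are typical venous-phase Hounsfield units (muscle ~55 HU,
#' fat ~-90 HU, trabecular-ish bone 400 HU).
#'
#' @param shape Grid size `(nx, ny, nz)`; nz >= 3.
#' @param spacing Voxel spacing `(sx, sy, sz)` mm.
#' @param muscle_hu,fat_hu,bone_hu Mean tissue intensities (HU).
#' @param muscle_sd Within-muscle HU texture standard deviation.
#' @param noise_sd Additive Gaussian image noise (HU); applied to the image
#'   only, never the mask.
#' @param tube_radius_mm Base (mid-volume) radius of each muscle tube.
#' @param tube_offset_mm Lateral distance of each tube centre from the
#'   midline bone column.
#' @param tube_extent Fraction of the z range the tubes span, centred;
#'   the radius tapers parabolically to zero at the ends so the muscle does
#'   not reach the first/last slices.
#' @param deform_amplitude_mm Pointwise standard deviation of the smooth
#'   random displacement field (mm); 0 disables deformation.
#' @param deform_scale_mm Gaussian smoothness scale of the field (mm).
#' @param volume_scale_range Per-case multiplicative radius scale is drawn
#'   uniformly from this range, driving inter-case volume variability.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(64, 64, 24),
                           spacing = c(2, 2, 5),
                           muscle_hu = 55, muscle_sd = 6,
                           fat_hu = -90, bone_hu = 400,
                           noise_sd = 12,
                           tube_radius_mm = 9,
                           tube_offset_mm = 22,
                           tube_extent = 0.7,
                           deform_amplitude_mm = 2.5,
                           deform_scale_mm = 14,
                           volume_scale_range = c(0.8, 1.2)) {
  p <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
            muscle_hu = muscle_hu, muscle_sd = muscle_sd, fat_hu = fat_hu,
            bone_hu = bone_hu, noise_sd = noise_sd,
            tube_radius_mm = tube_radius_mm, tube_offset_mm = tube_offset_mm,
            tube_extent = tube_extent,
            deform_amplitude_mm = deform_amplitude_mm,
            deform_scale_mm = deform_scale_mm,
            volume_scale_range = as.numeric(volume_scale_range))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

#' @noRd
validate_phantom_params <- function(p) {
  if (any(p$shape < 3L))
    stop("phantom grid must be at least 3 voxels per axis", call. = FALSE)
  if (any(p$spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$tube_radius_mm <= 0) stop("tube_radius_mm must be > 0", call. = FALSE)
  if (p$tube_extent <= 0 || p$tube_extent > 1)
    stop("tube_extent must be in (0, 1]", call. = FALSE)
  r <- p$volume_scale_range
  if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
    stop("volume_scale_range must be 0 < min <= max", call. = FALSE)
  # the scaled tube plus offset must fit inside the body ellipse
  fov <- p$shape[1:2] * p$spacing[1:2]
  if (p$tube_offset_mm + p$tube_radius_mm * r[2] > 0.45 * min(fov))
    stop("grid too small to contain the muscle tubes at this radius/offset",
         call. = FALSE)
  invisible(p)
}

# Tube radius profile along z (mm): parabolic taper to zero at the extent
# ends. Exported through phantom_tube_volume() for analytic checks.
#' @noRd
.tube_radius_profile <- function(z_mm, z_mid, z_half, base_radius) {
  u <- (z_mm - z_mid) / z_half
  r2 <- 1 - u^2
  base_radius * sqrt(pmax(r2, 0))
}

#' Analytic volume of the phantom's muscle tubes
#'
#' Integrates the parabolic radius profile (a closed form exists:
#' each tube is a paraboloid-of-revolution pair with volume
#' `pi * r^2 * z_half * 4/3`), returning the bilateral volume in cm^3 for a
#' given per-case radius scale. Used to validate the voxelized mask volume.
#'
#' @param params A [phantom_params()].
#' @param scale Per-case radius scale.
#' @return Bilateral tube volume in cm^3.
#' @export
phantom_tube_volume <- function(params, scale = 1) {
  z_len <- params$shape[3] * params$spacing[3]
  z_half <- params$tube_extent * z_len / 2
  r <- params$tube_radius_mm * scale
  # integral of pi r^2 (1 - u^2) over u in [-1,1] times z_half
  vol_mm3 <- pi * r^2 * z_half * (2 - 2 / 3)
  2 * vol_mm3 / 1000
}

# Smooth random displacement field: white noise smoothed at the given scale,
# rescaled so its pointwise standard deviation equals `amplitude_mm`.
#' @noRd
.random_displacement <- function(shape, spacing, amplitude_mm, scale_mm) {
  comps <- vector("list", 3)
  for (d in 1:3) {
    w <- array(stats::rnorm(prod(shape)), shape)
    w <- gauss_smooth3(w, scale_mm / spacing)
    s <- stats::sd(as.vector(w))
    comps[[d]] <- if (s > 0) w * (amplitude_mm / s) else w * 0
  }
  comps
}

#' Generate one phantom case
#'
#' Builds the undeformed anatomy (fat body ellipse, bone column, two muscle
#' tubes), applies one shared smooth displacement field to image and mask by
#' backward warping (linear interpolation for the image, nearest neighbour
#' for the mask), then adds Gaussian HU noise to the image only. The mask is
#' the exact deformed tube support.
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed; identical `(params, seed)` give voxel-identical
#'   output.
#' @param case_id Case identifier.
#' @return A list with elements `image` ([image_volume()]), `mask`
#'   ([binary_mask()]), `scale` (drawn radius scale) and `seed`.
#' @export
generate_case <- function(params, seed, case_id = sprintf("case_%03d", seed)) {
  stopifnot(inherits(params, "phantom_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  nx <- params$shape[1]; ny <- params$shape[2]; nz <- params$shape[3]
  sp <- params$spacing
  scale <- stats::runif(1, params$volume_scale_range[1],
                        params$volume_scale_range[2])

  # physical coordinates of voxel centres
  xs <- (seq_len(nx) - 0.5) * sp[1]
  ys <- (seq_len(ny) - 0.5) * sp[2]
  zs <- (seq_len(nz) - 0.5) * sp[3]
  cx <- nx * sp[1] / 2; cy <- ny * sp[2] / 2
  X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))

  # body ellipse: fills most of the field of view
  ax <- 0.46 * nx * sp[1]; ay <- 0.42 * ny * sp[2]
  body <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1

  # bone column: cylinder slightly posterior of centre
  bone_cy <- cy + 0.12 * ny * sp[2]
  bone <- (X - cx)^2 + (Y - bone_cy)^2 <= 8^2

  # two muscle tubes flanking the column, tapering toward first/last slices
  z_mid <- nz * sp[3] / 2
  z_half <- params$tube_extent * nz * sp[3] / 2
  rprof <- .tube_radius_profile(Z, z_mid, z_half, params$tube_radius_mm * scale)
  tube_cy <- cy + 0.10 * ny * sp[2]
  off <- params$tube_offset_mm
  tubeL <- (X - (cx - off))^2 + (Y - tube_cy)^2 <= rprof^2
  tubeR <- (X - (cx + off))^2 + (Y - tube_cy)^2 <= rprof^2
  tubes <- tubeL | tubeR

  img <- array(-1000, c(nx, ny, nz))
  img[body] <- params$fat_hu
  img[bone] <- params$bone_hu
  texture <- array(stats::rnorm(nx * ny * nz, 0, params$muscle_sd),
                   c(nx, ny, nz))
  img[tubes] <- params$muscle_hu + texture[tubes]

  mask <- tubes
  if (params$deform_amplitude_mm > 0) {
    disp <- .random_displacement(c(nx, ny, nz), sp,
                                 params$deform_amplitude_mm,
                                 params$deform_scale_mm)
    # backward warp: sample source at (voxel + displacement/spacing)
    xi <- as.vector(X / sp[1] + 0.5 + disp[[1]] / sp[1])
    yi <- as.vector(Y / sp[2] + 0.5 + disp[[2]] / sp[2])
    zi <- as.vector(Z / sp[3] + 0.5 + disp[[3]] / sp[3])
    img <- array(interp3_linear(img, xi, yi, zi, fill = -1000), c(nx, ny, nz))
    mask <- array(interp3_nearest(mask, xi, yi, zi, fill = 0) > 0,
                  c(nx, ny, nz))
  }
  if (params$noise_sd > 0)
    img <- img + array(stats::rnorm(nx * ny * nz, 0, params$noise_sd),
                       c(nx, ny, nz))

  list(image = image_volume(img, sp, case_id = case_id),
       mask = binary_mask(mask, sp, case_id = case_id, label = "bilateral"),
       scale = scale, seed = as.integer(seed))
}

#' Generate a phantom cohort
#'
#' Per-case seeds are drawn up-front from the master seed (one
#' `sample.int()` call), so each case is reproducible independently of
#' generation order.
#'
#' @param n Number of cases (>= 2; cross-validation needs at least two).
#' @param params A [phantom_params()].
#' @param master_seed Integer master seed.
#' @return A list of class `phantom_cohort`; each element is a
#'   [generate_case()] result with a distinct `case_id`.
#' @export
generate_cohort <- function(n, params = phantom_params(), master_seed = 1) {
  if (n < 2) stop("cohort needs n >= 2 cases", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(master_seed))
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cohort <- lapply(seq_len(n), function(i) {
    generate_case(params, case_seeds[i], case_id = sprintf("case_%03d", i))
  })
  structure(cohort, class = "phantom_cohort", master_seed = master_seed)
}

#' Write a phantom cohort to disk
#'
#' Writes `case_XXX_img.nii.gz` / `case_XXX_mask.nii.gz` pairs plus a
#' `manifest.csv` with case_id, seed, radius scale and true volume (cm^3).
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data.frame, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(cs) {
    write_volume(cs$image, file.path(out_dir, paste0(cs$image$case_id, "_img.nii.gz")))
    write_mask(cs$mask, file.path(out_dir, paste0(cs$mask$case_id, "_mask.nii.gz")))
    data.frame(case_id = cs$image$case_id, seed = cs$seed, scale = cs$scale,
               true_volume_cm3 = compute_volume(cs$mask))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir Directory containing `*_img.nii.gz` / `*_mask.nii.gz` pairs.
#' @return A list of `(image, mask)` pairs.
#' @export
read_cohort <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "_img\\.nii(\\.gz)?$",
                          full.names = TRUE))
  if (length(imgs) == 0)
    stop(sprintf("no '*_img.nii.gz' volumes found in '%s'", dir),
         call. = FALSE)
  lapply(imgs, function(f) {
    id <- sub("_img\\.nii(\\.gz)?$", "", basename(f))
    mf <- file.path(dir, paste0(id, "_mask.nii.gz"))
    if (!file.exists(mf)) mf <- file.path(dir, paste0(id, "_mask.nii"))
    list(image = read_volume(f, case_id = id),
         mask = read_mask(mf, case_id = id))
  })
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
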