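# Dual-stage intensity-based registration:
#   stage 1 — multi-resolution affine alignment minimizing mean squared
#             error by gradient descent (coarse-to-fine pyramid, each level
#             initialized from the previous one);
#   stage 2 — B-spline free-form deformation maximizing mutual information
#             (joint-histogram, cubic Parzen window on the moving
#             intensity) by stochastic gradient descent on a random voxel
#             subsample.
# The final (minimized) energy, defined as the negative mutual information
# at convergence, ranks atlas fits.

#' Affine stage configuration
#'
#' @param pyramid Downsampling factors, coarse to fine, strictly
#'   decreasing, last must be 1. Levels whose downsampled grid would fall
#'   below `min_level_size` voxels on any axis are dropped automatically.
#' @param iterations Gradient-descent iterations per pyramid level.
#' @param step_mm Initial step length in mm of voxel displacement; decays
#'   linearly to 10% over the iterations of each level.
#' @param min_level_size Minimum level grid size per axis.
#' @param max_samples Cap on the number of voxel samples used per level
#'   (a deterministic stride through the grid); keeps fine-level cost
#'   bounded.
#' @return List of class `affine_config`.
#' @export
affine_config <- function(pyramid = c(8, 4, 2, 1), iterations = 60,
                          step_mm = 4, min_level_size = 4,
                          max_samples = 10000) {
  pyramid <- as.integer(pyramid)
  if (any(diff(pyramid) >= 0) || pyramid[length(pyramid)] != 1L ||
      any(pyramid < 1L))
    stop("pyramid factors must be strictly decreasing and end at 1",
         call. = FALSE)
  structure(list(pyramid = pyramid, iterations = as.integer(iterations),
                 step_mm = step_mm, metric = "mse",
                 min_level_size = as.integer(min_level_size),
                 max_samples = as.integer(max_samples)),
            class = "affine_config")
}

#' B-spline stage configuration
#'
#' @param grid_spacing_mm Control-point spacing in mm (scalar or length 3);
#'   must exceed the voxel spacing.
#' @param bins Joint-histogram bin count for mutual information.
#' @param iterations Gradient-descent iterations.
#' @param sampling_fraction Fraction of voxels sampled (once, seeded) for
#'   the stochastic metric evaluation.
#' @param step_mm Initial control-point step in mm; decays linearly to 10%.
#' @param max_samples Absolute cap on the metric subsample size.
#' @return List of class `bspline_config`.
#' @export
bspline_config <- function(grid_spacing_mm = 20, bins = 32, iterations = 30,
                           sampling_fraction = 0.25, step_mm = 1.5,
                           max_samples = 6000) {
  if (length(grid_spacing_mm) == 1) grid_spacing_mm <- rep(grid_spacing_mm, 3)
  if (any(grid_spacing_mm <= 0)) stop("grid spacing must be > 0", call. = FALSE)
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]", call. = FALSE)
  structure(list(grid_spacing_mm = as.numeric(grid_spacing_mm),
                 bins = as.integer(bins), metric = "mutual-information",
                 optimizer = "stochastic-gradient-descent",
                 iterations = as.integer(iterations),
                 sampling_fraction = sampling_fraction, step_mm = step_mm,
                 max_samples = as.integer(max_samples)),
            class = "bspline_config")
}

#' Build an atlas from an annotated case
#'
#' @param image An [image_volume()].
#' @param mask Its bilateral ground-truth [binary_mask()].
#' @return List of class `atlas`.
#' @export
atlas <- function(image, mask) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "binary_mask"))
  stop_if_grid_mismatch(image, mask, "atlas image/mask")
  structure(list(image = image, mask = mask, case_id = image$case_id),
            class = "atlas")
}

# physical coordinates (mm) of all voxel centres of a grid
#' @noRd
.grid_points <- function(d, spacing) {
  xs <- (seq_len(d[1]) - 0.5) * spacing[1]
  ys <- (seq_len(d[2]) - 0.5) * spacing[2]
  zs <- (seq_len(d[3]) - 0.5) * spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

# apply affine params (A col-major 9, t 3) about centre `cen` to points P
#' @noRd
.affine_apply <- function(params, P, cen) {
  A <- matrix(params[1:9], 3, 3)
  t(A %*% (t(P) - cen) + cen + params[10:12])
}

# Single-level affine MSE gradient descent. P: fixed sample points (mm),
# fval: fixed intensities, mov: moving array, msp: moving spacing.
#' @noRd
.affine_level <- function(params, P, fval, mov, msp, cen, iterations,
                          step0, fill) {
  g_mov <- gradient3(mov, msp)
  n <- nrow(P)
  extent <- max(dim(mov) * msp)
  sc <- c(rep(extent, 9), rep(1, 3))  # mm of displacement per unit param
  for (it in seq_len(iterations)) {
    Q <- .affine_apply(params, P, cen)
    xi <- Q[, 1] / msp[1] + 0.5
    yi <- Q[, 2] / msp[2] + 0.5
    zi <- Q[, 3] / msp[3] + 0.5
    mval <- interp3_linear(mov, xi, yi, zi, fill = fill)
    r <- fval - mval
    if (!all(is.finite(r))) return(list(params = params, energy = Inf))
    gx <- interp3_linear(g_mov[[1]], xi, yi, zi)
    gy <- interp3_linear(g_mov[[2]], xi, yi, zi)
    gz <- interp3_linear(g_mov[[3]], xi, yi, zi)
    # dE/dA[i,j] = -2 mean(r * gM_i * (p - c)_j); dE/dt_i = -2 mean(r * gM_i)
    rg <- cbind(r * gx, r * gy, r * gz)
    Pc <- sweep(P, 2, cen)
    gA <- -2 * crossprod(rg, Pc) / n      # 3x3, rows = i, cols = j
    gt <- -2 * colMeans(rg)
    grad <- c(as.vector(gA), gt)
    # precondition: q = p * sc has mm-of-displacement units, so steepest
    # descent in q-space treats matrix and translation entries comparably
    gq <- grad / sc
    nq <- sqrt(sum(gq^2))
    if (nq < 1e-12) break
    step <- step0 * (1 - 0.9 * (it - 1) / max(1, iterations - 1))
    params <- params - step * (gq / nq) / sc
  }
  Q <- .affine_apply(params, P, cen)
  mval <- interp3_linear(mov, Q[, 1] / msp[1] + 0.5, Q[, 2] / msp[2] + 0.5,
                         Q[, 3] / msp[3] + 0.5, fill = fill)
  list(params = params, energy = mean((fval - mval)^2))
}

#' Multi-resolution affine registration
#'
#' Aligns `moving` to `target` by minimizing the mean squared intensity
#' error with gradient descent over a coarse-to-fine pyramid; each level is
#' initialized from the previous one.
#'
#' @param target,moving [image_volume()] objects.
#' @param cfg An [affine_config()].
#' @param fill Background intensity for out-of-grid samples (HU).
#' @return List with `params` (9 matrix + 3 translation entries, applied
#'   about the target centre), `centre`, `energy` (final MSE) and
#'   `pyramid_used`.
#' @export
register_affine <- function(target, moving, cfg = affine_config(),
                            fill = -1000) {
  stopifnot(inherits(target, "image_volume"), inherits(moving, "image_volume"))
  d <- dim(target$voxels)
  keep <- vapply(cfg$pyramid, function(f) all(d %/% f >= cfg$min_level_size),
                 logical(1))
  pyr <- cfg$pyramid[keep]
  if (length(pyr) == 0) pyr <- 1L
  cen <- d * target$spacing / 2
  params <- c(as.vector(diag(3)), 0, 0, 0)
  energy <- Inf
  for (f in pyr) {
    ft <- downsample3(target$voxels, f)
    fm <- downsample3(moving$voxels, f)
    tsp <- target$spacing * f
    msp <- moving$spacing * f
    P <- .grid_points(dim(ft), tsp)
    fv <- as.vector(ft)
    if (nrow(P) > cfg$max_samples) {
      sel <- unique(round(seq(1, nrow(P), length.out = cfg$max_samples)))
      P <- P[sel, , drop = FALSE]
      fv <- fv[sel]
    }
    res <- .affine_level(params, P, fv, fm, msp, cen,
                         cfg$iterations, cfg$step_mm * f, fill)
    params <- res$params
    energy <- res$energy
    if (!is.finite(energy)) break
  }
  list(params = params, centre = cen, energy = energy, pyramid_used = pyr)
}

# cubic B-spline basis weights and derivative for local coordinate u in [0,1)
#' @noRd
.bspline_w <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

#' @noRd
.bspline_dw <- function(u) {
  cbind(-(1 - u)^2 / 2,
        (9 * u^2 - 12 * u) / 6,
        (-9 * u^2 + 6 * u + 3) / 6,
        u^2 / 2)
}

# Tensor-product cubic B-spline basis at sample points P (mm): for each of
# the 64 neighbouring control points, the flat control index `j` and weight
# `v` per sample. Kept as plain vectors so applying the basis and its
# adjoint are indexed accumulations (no sparse-matrix machinery needed).
#' @noRd
.bspline_basis <- function(P, extent, h) {
  idx <- vector("list", 3); wts <- vector("list", 3); ncp <- integer(3)
  for (ax in 1:3) {
    t <- P[, ax] / h[ax]
    i0 <- floor(t)
    u <- t - i0
    # control points i0-1 .. i0+2, grid indices from -1 .. K+1
    K <- ceiling(extent[ax] / h[ax])
    ncp[ax] <- K + 3L          # indices -1..K+1 mapped to 1..K+3
    idx[[ax]] <- outer(i0, c(-1, 0, 1, 2), "+") + 2L   # 1-based
    idx[[ax]][idx[[ax]] < 1L] <- 1L
    idx[[ax]][idx[[ax]] > ncp[ax]] <- ncp[ax]
    wts[[ax]] <- .bspline_w(u)
  }
  offsets <- vector("list", 64L)
  k <- 1L
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    offsets[[k]] <- list(
      j = (idx[[3]][, cc] - 1L) * ncp[1] * ncp[2] +
        (idx[[2]][, b] - 1L) * ncp[1] + idx[[1]][, a],
      v = wts[[1]][, a] * wts[[2]][, b] * wts[[3]][, cc])
    k <- k + 1L
  }
  list(offsets = offsets, ncp = prod(ncp))
}

# displacement field U (n x 3) from coefficients (ncp x 3)
#' @noRd
.bspline_apply <- function(basis, coef) {
  U <- matrix(0, length(basis$offsets[[1]]$j), 3)
  for (o in basis$offsets) U <- U + coef[o$j, , drop = FALSE] * o$v
  U
}

# adjoint: accumulate per-sample forces (n x 3) onto control points
#' @noRd
.bspline_adjoint <- function(basis, force) {
  n <- nrow(force)
  J <- unlist(lapply(basis$offsets, `[[`, "j"), use.names = FALSE)
  V <- unlist(lapply(basis$offsets, `[[`, "v"), use.names = FALSE)
  acc <- rowsum(force[rep.int(seq_len(n), 64L), , drop = FALSE] * V,
                group = J, reorder = FALSE)
  g <- matrix(0, basis$ncp, 3)
  g[as.integer(rownames(acc)), ] <- acc
  g
}

# Dense n x ncp basis matrix; at desk problem sizes this is small enough
# that applying the basis and its adjoint become two BLAS products.
#' @noRd
.bspline_dense <- function(basis) {
  n <- length(basis$offsets[[1]]$j)
  W <- matrix(0, n, basis$ncp)
  rows <- seq_len(n)
  for (o in basis$offsets) {
    ij <- cbind(rows, o$j)
    W[ij] <- W[ij] + o$v
  }
  W
}

# Evaluate the B-spline displacement field on a full regular voxel grid by
# separable tensor contraction: one small dense basis matrix per axis
# (n_axis x ncp_axis) applied in sequence. Returns an n x 3 matrix in
# x-fastest voxel order, identical to applying the pointwise basis.
#' @noRd
.bspline_field_grid <- function(d, spacing, extent, h, coef) {
  Bs <- vector("list", 3); ncp <- integer(3)
  for (ax in 1:3) {
    p <- (seq_len(d[ax]) - 0.5) * spacing[ax]
    t <- p / h[ax]
    i0 <- floor(t)
    u <- t - i0
    K <- ceiling(extent[ax] / h[ax])
    ncp[ax] <- K + 3L
    w <- .bspline_w(u)
    B <- matrix(0, d[ax], ncp[ax])
    for (a in 1:4) {
      jc <- .clamp(i0 + (a - 2L) + 2L, 1L, ncp[ax])
      ij <- cbind(seq_len(d[ax]), jc)
      B[ij] <- B[ij] + w[, a]
    }
    Bs[[ax]] <- B
  }
  U <- matrix(0, prod(d), 3)
  for (dd in 1:3) {
    C <- array(coef[, dd], ncp)
    t1 <- Bs[[1]] %*% matrix(C, ncp[1], ncp[2] * ncp[3])
    A1 <- aperm(array(t1, c(d[1], ncp[2], ncp[3])), c(2, 1, 3))
    t2 <- Bs[[2]] %*% matrix(A1, ncp[2], d[1] * ncp[3])
    A2 <- aperm(array(t2, c(d[2], d[1], ncp[3])), c(3, 2, 1))
    t3 <- Bs[[3]] %*% matrix(A2, ncp[3], d[1] * d[2])
    U[, dd] <- as.vector(aperm(array(t3, c(d[3], d[1], d[2])), c(2, 3, 1)))
  }
  U
}

# Mattes-style mutual information between binned fixed values and moving
# values, plus the per-sample derivative of MI w.r.t. the moving intensity.
# fbin: precomputed fixed bin index (1..bins); returns list(mi, dmi_dm).
#' @noRd
.mi_and_gradient <- function(fbin, mval, mrange, bins, want_grad = TRUE) {
  n <- length(mval)
  dm <- (mrange[2] - mrange[1]) / (bins - 3)   # leave room for Parzen tails
  bm <- (mval - mrange[1]) / dm + 2            # continuous moving bin coord
  bm <- .clamp(bm, 2, bins - 1)
  j0 <- floor(bm)
  u <- bm - j0
  w <- .bspline_w(u)
  js <- outer(j0, c(-1, 0, 1, 2), "+")
  js[js < 1] <- 1; js[js > bins] <- bins
  joint <- matrix(0, bins, bins)               # rows fixed, cols moving
  for (k in 1:4) {
    acc <- rowsum(w[, k], group = (js[, k] - 1L) * bins + fbin)
    joint[as.integer(rownames(acc))] <- joint[as.integer(rownames(acc))] +
      acc[, 1]
  }
  joint <- joint / n
  pf <- rowSums(joint); pm <- colSums(joint)
  nzi <- joint > 0
  mi <- sum(joint[nzi] * log(joint[nzi] / (pf[row(joint)[nzi]] *
                                             pm[col(joint)[nzi]])))
  if (!want_grad) return(list(mi = mi, dmi_dm = NULL))
  # log-ratio table; zero cells contribute no gradient mass
  lr <- matrix(0, bins, bins)
  lr[nzi] <- log(joint[nzi] / (pf[row(joint)[nzi]] * pm[col(joint)[nzi]]))
  dw <- .bspline_dw(u)
  dmi <- numeric(n)
  for (k in 1:4) {
    dmi <- dmi + dw[, k] * lr[(js[, k] - 1L) * bins + fbin]
  }
  list(mi = mi, dmi_dm = dmi / (n * dm))
}

#' B-spline deformable registration stage
#'
#' Refines an affine alignment with a free-form deformation maximizing
#' mutual information. The deformation displaces the affine-mapped sample
#' position; its coefficients are optimized by gradient descent on a fixed
#' random voxel subsample with a linearly decaying step.
#'
#' @param target,moving [image_volume()] objects.
#' @param affine_params Result of [register_affine()].
#' @param cfg A [bspline_config()].
#' @param seed Seed for the voxel subsample.
#' @param fill Background intensity (HU).
#' @return List with `coef` (ncp x 3 coefficient matrix), `basis_spec`,
#'   `energy` (negative mutual information over all voxels, lower is
#'   better) and `mi_trace`.
#' @export
register_bspline <- function(target, moving, affine_params,
                             cfg = bspline_config(), seed = 1, fill = -1000) {
  d <- dim(target$voxels)
  tsp <- target$spacing; msp <- moving$spacing
  if (any(cfg$grid_spacing_mm <= tsp))
    stop("B-spline control grid spacing must exceed the voxel spacing",
         call. = FALSE)
  extent <- d * tsp
  h <- cfg$grid_spacing_mm
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  P_all <- .grid_points(d, tsp)
  fall <- as.vector(target$voxels)
  nall <- nrow(P_all)
  ns <- max(200L, as.integer(cfg$sampling_fraction * nall))
  ns <- min(ns, cfg$max_samples, nall)
  sel <- sample.int(nall, ns)
  P <- P_all[sel, , drop = FALSE]
  fval <- fall[sel]

  bins <- cfg$bins
  frange <- range(fall)
  fbin_all <- .clamp(floor((fall - frange[1]) /
                             ((frange[2] - frange[1]) / (bins - 1))) + 1L,
                     1L, bins)
  fbin <- fbin_all[sel]
  mrange <- range(as.vector(moving$voxels))
  if (mrange[2] - mrange[1] < 1e-9) mrange[2] <- mrange[1] + 1

  bas <- .bspline_basis(P, extent, h)
  # dense basis turns apply/adjoint into BLAS products when it fits
  Wd <- if (as.double(ns) * bas$ncp <= 2e7) .bspline_dense(bas) else NULL
  g_mov <- gradient3(moving$voxels, msp)
  Q0 <- .affine_apply(affine_params$params, P, affine_params$centre)
  coef <- matrix(0, bas$ncp, 3)
  mi_trace <- numeric(cfg$iterations)

  for (it in seq_len(cfg$iterations)) {
    Q <- Q0 + if (is.null(Wd)) .bspline_apply(bas, coef) else Wd %*% coef
    xi <- Q[, 1] / msp[1] + 0.5
    yi <- Q[, 2] / msp[2] + 0.5
    zi <- Q[, 3] / msp[3] + 0.5
    mval <- interp3_linear(moving$voxels, xi, yi, zi, fill = fill)
    res <- .mi_and_gradient(fbin, mval, mrange, bins)
    mi_trace[it] <- res$mi
    if (!is.finite(res$mi))
      return(list(coef = coef, energy = Inf, mi_trace = mi_trace,
                  basis_spec = list(extent = extent, h = h)))
    gx <- interp3_linear(g_mov[[1]], xi, yi, zi)
    gy <- interp3_linear(g_mov[[2]], xi, yi, zi)
    gz <- interp3_linear(g_mov[[3]], xi, yi, zi)
    # energy = -MI; force per sample = -dMI/dm * gradM
    force <- cbind(res$dmi_dm * gx, res$dmi_dm * gy, res$dmi_dm * gz)
    grad <- if (is.null(Wd)) -.bspline_adjoint(bas, force) else
      -crossprod(Wd, force)
    gn <- max(abs(grad))
    if (gn < 1e-14) break
    step <- cfg$step_mm * (1 - 0.9 * (it - 1) / max(1, cfg$iterations - 1))
    coef <- coef - step * grad / gn
  }

  # converged metric value on the (seeded, fixed) subsample
  Qf <- Q0 + if (is.null(Wd)) .bspline_apply(bas, coef) else Wd %*% coef
  mval_f <- interp3_linear(moving$voxels, Qf[, 1] / msp[1] + 0.5,
                           Qf[, 2] / msp[2] + 0.5, Qf[, 3] / msp[3] + 0.5,
                           fill = fill)
  mi_final <- .mi_and_gradient(fbin, mval_f, mrange, bins,
                               want_grad = FALSE)$mi
  list(coef = coef, energy = -mi_final, mi_trace = mi_trace,
       basis_spec = list(extent = extent, h = h))
}

# total transform target-point -> moving-point for a registration outcome
#' @noRd
.total_transform <- function(P, affine, bspline) {
  Q <- .affine_apply(affine$params, P, affine$centre)
  if (!is.null(bspline)) {
    bas <- .bspline_basis(P, bspline$basis_spec$extent, bspline$basis_spec$h)
    Q <- Q + .bspline_apply(bas, bspline$coef)
  }
  Q
}

#' Register one atlas to a target volume
#'
#' Runs the dual-stage registration (affine then, unless `bspline_cfg` is
#' `NULL`, B-spline refinement), then propagates the atlas mask to the
#' target grid with nearest-neighbour interpolation. The outcome's
#' `final_energy` is the minimized metric of the last stage run (MSE after
#' affine-only, negative mutual information otherwise); lower is a better
#' fit, and the value ranks atlases in [mas_segment()].
#'
#' @param target Target [image_volume()].
#' @param atl An [atlas()].
#' @param affine_cfg An [affine_config()].
#' @param bspline_cfg A [bspline_config()], or `NULL` for affine-only.
#' @param seed Seed for the stochastic metric subsample.
#' @return List of class `registration_outcome`: `affine`, `bspline`,
#'   `final_energy`, `warped_mask`, `case_id`, `success`.
#' @export
register_pair <- function(target, atl, affine_cfg = affine_config(),
                          bspline_cfg = bspline_config(), seed = 1) {
  stopifnot(inherits(atl, "atlas"))
  aff <- register_affine(target, atl$image, affine_cfg)
  bsp <- NULL
  energy <- aff$energy
  if (!is.null(bspline_cfg) && is.finite(energy)) {
    bsp <- register_bspline(target, atl$image, aff, bspline_cfg, seed = seed)
    energy <- bsp$energy
  }
  success <- is.finite(energy)
  d <- dim(target$voxels)
  warped <- array(FALSE, d)
  if (success) {
    P <- .grid_points(d, target$spacing)
    Q <- .affine_apply(aff$params, P, aff$centre)
    if (!is.null(bsp))
      Q <- Q + .bspline_field_grid(d, target$spacing, bsp$basis_spec$extent,
                                   bsp$basis_spec$h, bsp$coef)
    msp <- atl$image$spacing
    warped <- array(interp3_nearest(atl$mask$voxels, Q[, 1] / msp[1] + 0.5,
                                    Q[, 2] / msp[2] + 0.5,
                                    Q[, 3] / msp[3] + 0.5, fill = 0) > 0, d)
  } else {
    warning(sprintf("registration of atlas '%s' diverged (non-finite energy); excluded from ranking",
                    atl$case_id))
  }
  structure(list(affine = aff, bspline = bsp, final_energy = energy,
                 warped_mask = binary_mask(warped, target$spacing,
                                           case_id = atl$case_id,
                                           label = "bilateral"),
                 case_id = atl$case_id, success = success),
            class = "registration_outcome")
}
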