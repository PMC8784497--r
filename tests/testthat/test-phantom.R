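test_that("same parameters and seed give voxel-identical cases", {
  p <- tiny_phantom_params()
  a <- generate_case(p, 42)
  b <- generate_case(p, 42)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  d <- generate_case(p, 43)
  expect_false(identical(a$image$voxels, d$image$voxels))
})

test_that("undeformed noise-free mask volume matches the analytic tube volume", {
  p <- phantom_params(deform_amplitude_mm = 0, noise_sd = 0,
                      volume_scale_range = c(1, 1))
  cs <- generate_case(p, 1)
  vol <- compute_volume(cs$mask)
  vol_true <- phantom_tube_volume(p, 1)
  # tolerance: one voxel-volume per boundary voxel of the discretized tubes
  vox <- cs$mask$voxels
  interior <- vox &
    pmmseg:::shift_axis(vox, 1, 1L) & pmmseg:::shift_axis(vox, 1, -1L) &
    pmmseg:::shift_axis(vox, 2, 1L) & pmmseg:::shift_axis(vox, 2, -1L) &
    pmmseg:::shift_axis(vox, 3, 1L) & pmmseg:::shift_axis(vox, 3, -1L)
  n_boundary <- sum(vox) - sum(interior)
  tol <- n_boundary * prod(p$spacing) / 1000
  expect_lt(abs(vol - vol_true), tol)
})

test_that("muscle mask lies inside the body and off the first/last slices", {
  p <- phantom_params()
  cs <- generate_case(p, 9)
  # mask voxels must sit on soft tissue, not air
  expect_true(all(cs$image$voxels[cs$mask$voxels] > -400))
  nz <- dim(cs$mask$voxels)[3]
  expect_equal(sum(cs$mask$voxels[, , 1]), 0)
  expect_equal(sum(cs$mask$voxels[, , nz]), 0)
})

test_that("bilateral mask has one connected component per side at gentle deformation", {
  p <- phantom_params()
  cs <- generate_case(p, 17)
  # split at the midline: each half must be a single 6-connected component
  n_components <- function(vox) {
    d <- dim(vox); lab <- array(0L, d); nxt <- 0L
    idx <- which(vox)
    for (start in idx) {
      if (lab[start] > 0) next
      nxt <- nxt + 1L
      queue <- start
      lab[start] <- nxt
      while (length(queue) > 0) {
        cur <- queue[1]; queue <- queue[-1]
        k <- arrayInd(cur, d)
        for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                         c(0,0,1), c(0,0,-1))) {
          nb <- k + off
          if (all(nb >= 1) && all(nb <= d)) {
            li <- ((nb[3] - 1) * d[2] + (nb[2] - 1)) * d[1] + nb[1]
            if (vox[li] && lab[li] == 0L) { lab[li] <- nxt; queue <- c(queue, li) }
          }
        }
      }
    }
    nxt
  }
  d <- dim(cs$mask$voxels)
  half <- d[1] %/% 2
  left <- cs$mask$voxels[1:half, , , drop = FALSE]
  right <- cs$mask$voxels[(half + 1):d[1], , , drop = FALSE]
  expect_equal(n_components(left), 1L)
  expect_equal(n_components(right), 1L)
})

test_that("cohorts are reproducible with distinct case ids and seeds", {
  p <- tiny_phantom_params()
  a <- generate_cohort(6, p, master_seed = 5)
  b <- generate_cohort(6, p, master_seed = 5)
  ids <- vapply(a, function(cs) cs$image$case_id, character(1))
  expect_equal(length(unique(ids)), 6L)
  expect_identical(a[[3]]$image$voxels, b[[3]]$image$voxels)
  expect_error(generate_cohort(1, p, 1), "n >= 2")
})

test_that("cohort volume variability reflects the configured scale range", {
  # volumes scale with the squared radius factor; for scale ~ U(0.8, 1.2)
  # the implied coefficient of variation of scale^2 is ~0.228
  p <- tiny_phantom_params(deform_amplitude_mm = 0, noise_sd = 0)
  cohort <- generate_cohort(120, p, master_seed = 11)
  vols <- vapply(cohort, function(cs) compute_volume(cs$mask), numeric(1))
  cv <- stats::sd(vols) / mean(vols)
  s <- seq(0.8, 1.2, length.out = 20001)^2
  cv_implied <- stats::sd(s) / mean(s)
  expect_gt(cv, 0.6 * cv_implied)
  expect_lt(cv, 1.4 * cv_implied)
})

test_that("image and mask share one displacement field", {
  # with zero noise, interior mask voxels keep pure muscle intensity after
  # warping (boundary voxels legitimately blend under linear image
  # interpolation); a differing mask warp would decouple the two
  p <- phantom_params(noise_sd = 0, muscle_sd = 0)
  cs <- generate_case(p, 23)
  vox <- cs$mask$voxels
  interior <- vox &
    pmmseg:::shift_axis(vox, 1, 1L) & pmmseg:::shift_axis(vox, 1, -1L) &
    pmmseg:::shift_axis(vox, 2, 1L) & pmmseg:::shift_axis(vox, 2, -1L) &
    pmmseg:::shift_axis(vox, 3, 1L) & pmmseg:::shift_axis(vox, 3, -1L)
  expect_gt(sum(interior), 100)
  frac_muscle <- mean(abs(cs$image$voxels[interior] - p$muscle_hu) < 5)
  expect_gt(frac_muscle, 0.95)
})

test_that("cohort round-trips through the on-disk layout", {
  p <- tiny_phantom_params()
  cohort <- generate_cohort(3, p, master_seed = 2)
  d <- file.path(tempdir(), "cohort_rt")
  manifest <- write_cohort(cohort, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_equal(nrow(manifest), 3L)
  back <- read_cohort(d)
  expect_equal(length(back), 3L)
  expect_identical(back[[2]]$mask$voxels, cohort[[2]]$mask$voxels)
  expect_equal(back[[2]]$image$spacing, cohort[[2]]$image$spacing)
  unlink(d, recursive = TRUE)
})
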