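test_that("cubic B-spline weights form a partition of unity", {
  u <- seq(0, 0.999, length.out = 50)
  w <- pmmseg:::.bspline_w(u)
  expect_equal(rowSums(w), rep(1, 50))
  dw <- pmmseg:::.bspline_dw(u)
  expect_equal(rowSums(dw), rep(0, 50), tolerance = 1e-12)
  # derivative consistent with finite differences of the weights
  eps <- 1e-6
  num <- (pmmseg:::.bspline_w(u + eps) - pmmseg:::.bspline_w(u - eps)) / (2 * eps)
  expect_equal(dw, num, tolerance = 1e-8)
})

test_that("separable grid evaluation equals the pointwise tensor basis", {
  set.seed(12)
  d <- c(10, 9, 6); spacing <- c(2, 2, 5)
  extent <- d * spacing
  h <- c(10, 10, 12)
  ncp <- prod(ceiling(extent / h) + 3)
  coef <- matrix(rnorm(ncp * 3), ncp, 3)
  P <- pmmseg:::.grid_points(d, spacing)
  bas <- pmmseg:::.bspline_basis(P, extent, h)
  U_pt <- pmmseg:::.bspline_apply(bas, coef)
  U_gr <- pmmseg:::.bspline_field_grid(d, spacing, extent, h, coef)
  expect_equal(U_gr, U_pt, tolerance = 1e-12)
  # dense basis path agrees too
  W <- pmmseg:::.bspline_dense(bas)
  expect_equal(unname(W %*% coef), U_pt, tolerance = 1e-12)
})

test_that("affine stage recovers a known in-plane translation", {
  p <- tiny_phantom_params(deform_amplitude_mm = 0)
  cs <- generate_case(p, 21)
  v <- cs$image$voxels
  d <- dim(v)
  shift <- 2L  # voxels, (2, 2, 0)
  tr <- array(-1000, d)
  tr[(shift + 1):d[1], (shift + 1):d[2], ] <-
    v[1:(d[1] - shift), 1:(d[2] - shift), ]
  target <- image_volume(tr, cs$image$spacing, case_id = "shifted")
  out <- register_pair(target, atlas(cs$image, cs$mask),
                       affine_config(pyramid = c(2, 1), iterations = 50),
                       bspline_cfg = NULL, seed = 1)
  trm <- array(FALSE, d)
  trm[(shift + 1):d[1], (shift + 1):d[2], ] <-
    cs$mask$voxels[1:(d[1] - shift), 1:(d[2] - shift), ]
  expect_gte(dsc(out$warped_mask, mk_mask(trm, cs$image$spacing)), 0.95)
  expect_true(out$success)
  expect_true(is.finite(out$final_energy))
})

test_that("warped mask stays on the target grid and registration is seeded-deterministic", {
  p <- tiny_phantom_params()
  a <- generate_case(p, 31, "a")
  t <- generate_case(p, 32, "t")
  cfg_a <- affine_config(pyramid = c(2, 1), iterations = 30)
  cfg_b <- bspline_config(grid_spacing_mm = 24, iterations = 10)
  o1 <- register_pair(t$image, atlas(a$image, a$mask), cfg_a, cfg_b, seed = 4)
  o2 <- register_pair(t$image, atlas(a$image, a$mask), cfg_a, cfg_b, seed = 4)
  expect_identical(o1$warped_mask$voxels, o2$warped_mask$voxels)
  expect_equal(o1$final_energy, o2$final_energy)
  expect_equal(dim(o1$warped_mask$voxels), dim(t$image$voxels))
  expect_equal(o1$warped_mask$spacing, t$image$spacing)
})

test_that("stage configurations validate their invariants", {
  expect_error(affine_config(pyramid = c(4, 8, 1)), "decreasing")
  expect_error(affine_config(pyramid = c(4, 2)), "end at 1")
  expect_error(bspline_config(grid_spacing_mm = -1), "> 0")
  expect_error(bspline_config(sampling_fraction = 0), "sampling_fraction")
  p <- tiny_phantom_params()
  cs <- generate_case(p, 1)
  # control grid must be coarser than the voxels
  expect_error(register_bspline(cs$image, cs$image,
                                list(params = c(diag(3), 0, 0, 0),
                                     centre = c(0, 0, 0)),
                                bspline_config(grid_spacing_mm = 1)),
               "exceed")
})
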