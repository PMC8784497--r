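cfg32 <- gan_config(train_size = 32, epochs = 1, batch_size = 1,
                    base_width = 4, seed = 11)

test_that("segmenter configuration enforces its invariants", {
  expect_error(gan_config(train_size = 48), "power of two")
  expect_error(gan_config(train_size = 16), "power of two")
  expect_error(gan_config(lambda_l1 = 0), "positive")
  expect_error(gan_config(lambda_gan = -1), "positive")
  cfg <- gan_config(train_size = 64)
  expect_equal(cfg$depth, 4L)       # log2(64) - 2 levels
  expect_equal(cfg$lambda_l1, 10)
  expect_equal(cfg$lambda_gan, 1)
  expect_equal(gan_config(train_size = 256)$train_size, 256L)
})

test_that("2.5D sampling yields n-2 samples with below/active/above channels", {
  # a 76-slice exam gives 74 interior samples
  set.seed(2)
  v76 <- image_volume(array(rnorm(8 * 8 * 76, 0, 100), c(8, 8, 76)),
                      c(2, 2, 5), case_id = "long")
  m76 <- mk_mask(array(FALSE, c(8, 8, 76)), c(2, 2, 5))
  s <- build_slice_samples(v76, m76, cfg32)
  expect_length(s, 74L)
  expect_equal(vapply(s, `[[`, numeric(1), "z"), as.numeric(2:75))
  # minimal case: 3 slices -> one sample built from slices 1, 2, 3
  v3 <- image_volume(array(seq_len(4 * 4 * 3), c(4, 4, 3)) * 1.0, c(1, 1, 5))
  s3 <- build_slice_samples(v3, NULL, cfg32)
  expect_length(s3, 1L)
  expect_equal(s3[[1]]$z, 2)
  ts <- cfg32$train_size
  for (ch in 1:3) {
    ref <- pmmseg:::resize2(pmmseg:::.normalize_hu(v3$voxels[, , ch],
                                                   cfg32$hu_window),
                            ts, ts, "bilinear")
    expect_equal(s3[[1]]$input[, , ch], ref)
  }
  expect_error(build_slice_samples(
    image_volume(array(0, c(4, 4, 3)), c(1, 1, 5))[["voxels"]], NULL, cfg32))
})

test_that("sample counts are conserved over a cohort", {
  p <- tiny_phantom_params()
  cohort <- generate_cohort(3, p, master_seed = 6)
  total <- sum(vapply(cohort, function(cs) {
    length(build_slice_samples(cs$image, cs$mask, cfg32))
  }, integer(1)))
  expect_equal(total, sum(vapply(cohort, function(cs) {
    dim(cs$image$voxels)[3] - 2L
  }, integer(1))))
})

test_that("resized labels remain strictly binary", {
  p <- tiny_phantom_params()
  cs <- generate_case(p, 4)
  s <- build_slice_samples(cs$image, cs$mask, cfg32)
  vals <- unique(unlist(lapply(s, function(x) unique(as.vector(x$label)))))
  expect_true(all(vals %in% c(0, 1)))
})

test_that("L1 loss matches element-wise brute force", {
  y <- matrix(0.5, 4, 4)
  expect_equal(l1_loss(y, y), 0)
  expect_equal(l1_loss(y, y + 0.3), 0.3)
  set.seed(21)
  for (i in 1:5) {
    a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
    brute <- sum(abs(b - a)) / 16
    expect_equal(l1_loss(a, b), brute)
  }
  expect_error(l1_loss(matrix(NaN, 2, 2), matrix(0, 2, 2)), "finite")
})

test_that("adversarial loss value matches its defining expectation", {
  set.seed(22)
  dr <- matrix(runif(9, 0.1, 0.9), 3, 3)
  df <- matrix(runif(9, 0.1, 0.9), 3, 3)
  expect_equal(gan_loss(dr, df), mean(log(dr)) + mean(log(1 - df)))
  expect_error(gan_loss(dr, df * 0), "strictly")
  expect_error(gan_loss(dr + 1, df), "strictly")
})

test_that("an untrained generator still yields a valid binary mask on the input grid", {
  p <- tiny_phantom_params()
  cs <- generate_case(p, 8)
  cfg0 <- gan_config(train_size = 32, epochs = 0, base_width = 4, seed = 5)
  s <- build_slice_samples(cs$image, cs$mask, cfg0)
  gen <- gan_train(s, cfg0)
  expect_true(is.finite(gen$trace$l1[1]))  # initialization loss recorded
  pred <- gan_predict(cs$image, gen)
  expect_s3_class(pred, "binary_mask")
  expect_equal(dim(pred$voxels), dim(cs$image$voxels))
  expect_equal(pred$spacing, cs$image$spacing)
  expect_type(pred$voxels, "logical")
})

test_that("training is repeatable for a fixed seed and records its loss trace", {
  p <- tiny_phantom_params()
  cs <- generate_case(p, 9)
  cfg <- gan_config(train_size = 32, epochs = 2, batch_size = 1,
                    base_width = 4, seed = 13, lr = 1e-3)
  s <- build_slice_samples(cs$image, cs$mask, cfg)[3:6]
  g1 <- gan_train(s, cfg)
  g2 <- gan_train(s, cfg)
  expect_identical(g1$trace, g2$trace)
  expect_identical(g1$params, g2$params)
  expect_equal(nrow(g1$trace), 3L)   # epoch 0 + 2 epochs
  expect_true(all(is.finite(g1$trace$l1)))
})

test_that("extreme generator outputs binarize to empty and full masks", {
  p <- tiny_phantom_params()
  cs <- generate_case(p, 10)
  cfg <- gan_config(train_size = 32, epochs = 0, base_width = 4, seed = 5)
  s <- build_slice_samples(cs$image, cs$mask, cfg)
  gen <- gan_train(s, cfg)
  # force the output conv bias to saturate the sigmoid either way
  gen_lo <- gen; gen_lo$params$out$b <- -50
  gen_hi <- gen; gen_hi$params$out$b <- 50
  expect_equal(sum(gan_predict(cs$image, gen_lo)$voxels), 0)
  expect_equal(sum(gan_predict(cs$image, gen_hi)$voxels),
               prod(dim(cs$image$voxels)))
})
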