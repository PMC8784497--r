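test_that("volume is voxel count times voxel volume, additive over disjoint masks", {
  v <- array(FALSE, c(20, 10, 10)); v[seq_len(1000)] <- TRUE
  expect_equal(compute_volume(mk_mask(v, spacing = c(1, 1, 5))), 5.0)
  expect_equal(compute_volume(mk_mask(array(FALSE, c(4, 4, 4)))), 0)
  a <- array(FALSE, c(8, 8, 4)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(8, 8, 4)); b[6:8, , ] <- TRUE
  sp <- c(2, 2, 5)
  expect_equal(compute_volume(mk_mask(a | b, sp)),
               compute_volume(mk_mask(a, sp)) + compute_volume(mk_mask(b, sp)))
})

test_that("dice coefficient matches its closed form and symmetry", {
  a <- random_mask(c(6, 6, 4), 0.4, seed = 1)
  expect_equal(dsc(a, a), 1)
  l <- array(FALSE, c(6, 6, 4)); l[1:3, , ] <- TRUE
  r <- array(FALSE, c(6, 6, 4)); r[4:6, , ] <- TRUE
  expect_equal(dsc(mk_mask(l), mk_mask(r)), 0)
  # |A|=4, |B|=6, |A n B|=3 -> 0.6
  x <- array(FALSE, c(4, 4, 3)); x[1:4] <- TRUE
  y <- array(FALSE, c(4, 4, 3)); y[2:7] <- TRUE
  expect_equal(dsc(mk_mask(x), mk_mask(y)), 0.6)
  b <- random_mask(c(6, 6, 4), 0.4, seed = 2)
  expect_equal(dsc(a, b), dsc(b, a))
  expect_true(dsc(a, b) >= 0 && dsc(a, b) <= 1)
  # both empty agree on absence
  e <- mk_mask(array(FALSE, c(6, 6, 4)))
  expect_equal(dsc(e, e), 1)
})

test_that("spearman correlation equals rank-then-Pearson and hits the poles", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, 2 * x + 1), 1)
  expect_equal(spearman_rho(x, -x), -1)
  set.seed(10)
  for (i in 1:5) {
    xs <- rnorm(10); ys <- rnorm(10)
    expect_equal(spearman_rho(xs, ys),
                 stats::cor(rank(xs), rank(ys), method = "pearson"))
  }
  expect_warning(rho <- spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(rho))
  expect_error(spearman_rho(1:3, 1:4), "lengths")
})

test_that("signed-rank test is exact: hand cases and full sign enumeration", {
  # identical pairs: degenerate, p = 1
  expect_warning(r0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(r0$p_value, 1)
  # n = 5 all positive differences: one tail 1/32, two-sided 1/16
  r5 <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(r5$p_value, 2 / 32)
  expect_equal(r5$statistic, 15)
  # enumeration oracle on random fixtures, including ties, n <= 12
  set.seed(77)
  for (i in 1:6) {
    n <- sample(6:12, 1)
    xs <- round(rnorm(n, 0, 2), 1)
    ys <- round(rnorm(n, 0.5, 2), 1)
    if (all(xs == ys)) next
    got <- suppressWarnings(wilcoxon_signed_rank(xs, ys))
    expect_equal(got$p_value, brute_wilcoxon_p(xs, ys),
                 tolerance = 1e-12, label = sprintf("fixture %d", i))
  }
  # tie-free case agrees with the standard exact implementation
  set.seed(5)
  xs <- rnorm(10); ys <- rnorm(10)
  ref <- stats::wilcox.test(xs, ys, paired = TRUE, exact = TRUE)
  expect_equal(wilcoxon_signed_rank(xs, ys)$p_value, ref$p.value)
})

test_that("signed-rank normal approximation is used above the exact limit", {
  set.seed(8)
  xs <- rnorm(30); ys <- rnorm(30, 0.4)
  got <- wilcoxon_signed_rank(xs, ys)
  expect_equal(got$method, "normal-approximation")
  ref <- stats::wilcox.test(xs, ys, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("volume error statistics reproduce their defining arithmetic", {
  t <- c(200, 239, 280)
  expect_equal(volume_error_stats(t, t),
               list(mean_signed_pct = 0, mean_squared_diff = 0, rmse = 0))
  # cohort means 308 vs 239 give +28.9% to one decimal
  pred <- t * 308 / 239
  expect_equal(round(volume_error_stats(pred, t)$mean_signed_pct, 1), 28.9)
  # constant shift: rmse equals the shift
  expect_equal(volume_error_stats(t + 7, t)$rmse, 7)
  expect_equal(volume_error_stats(t + 7, t)$mean_squared_diff, 49)
  expect_error(volume_error_stats(1:3, 1:4), "lengths")
})

test_that("folds partition the cohort with every case tested exactly once", {
  ids <- sprintf("case_%03d", 1:34)
  folds <- make_folds(ids, k = 5, seed = 3)
  sizes <- vapply(folds, function(f) length(f$test_ids), integer(1))
  expect_equal(sort(sizes, decreasing = TRUE), c(7, 7, 7, 7, 6))
  all_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_setequal(c(f$train_ids, f$test_ids), ids)
  }
  expect_identical(make_folds(ids, 5, seed = 3), folds)
  expect_false(identical(make_folds(ids, 5, seed = 4), folds))
  expect_error(make_folds(ids[1:3], 5), "fewer")
})

test_that("bootstrap median CI brackets the sample median deterministically", {
  x <- c(0.61, 0.72, 0.74, 0.75, 0.78, 0.81, 0.83, 0.85, 0.9, 0.92)
  ci <- median_ci(x, n_boot = 2000, seed = 9)
  expect_equal(unname(ci["median"]), stats::median(x))
  expect_lte(ci["lower"], ci["median"])
  expect_gte(ci["upper"], ci["median"])
  expect_identical(median_ci(x, n_boot = 2000, seed = 9), ci)
})
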