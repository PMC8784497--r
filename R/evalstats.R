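# Volumetry, overlap and cohort statistics: muscle volume from voxel
# counts, Dice overlap, Spearman rank correlation, an exact paired
# signed-rank test, volume-error summaries and bootstrap confidence
# intervals for medians.

#' Muscle volume of a mask in cm^3
#'
#' Number of foreground voxels times the voxel volume
#' (`sx * sy * sz` mm^3), converted to cm^3.
#'
#' @param mask A [binary_mask()].
#' @return Volume in cm^3.
#' @export
compute_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (any(!is.finite(mask$spacing)))
    stop("mask has no usable voxel spacing", call. = FALSE)
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` in `[0, 1]`. Two empty masks agree perfectly on
#' absence, so `dsc(empty, empty)` is defined as 1.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) return(1)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged), as computed by
#' `stats::cor(method = "spearman")`. Constant input has no defined rank
#' correlation and returns `NA` with a warning.
#'
#' @param xs,ys Equal-length numeric vectors, length >= 3.
#' @return rho in `[-1, 1]`, or `NA` for degenerate input.
#' @export
spearman_rho <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("lengths differ", call. = FALSE)
  if (length(xs) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(xs, ys, method = "spearman")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test on `xs - ys`. Zero differences are dropped. For
#' n <= `exact_max` pairs the null distribution of the positive-rank sum is
#' computed exactly by convolution over the (doubled, hence integer)
#' mid-ranks, so the exact p-value is available even under ties; above that,
#' the normal approximation with the usual tie correction is used. The test
#' is the cohort comparison of choice here because paired segmentation
#' scores are matched but not Gaussian.
#'
#' @param xs,ys Equal-length paired numeric vectors.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return List with `statistic` (positive-rank sum W+), `p_value`
#'   (two-sided), `n` (non-zero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(xs, ys, exact_max = 25) {
  if (length(xs) != length(ys)) stop("lengths differ", call. = FALSE)
  d <- xs - ys
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: each rank enters W+ independently with probability 1/2.
    # doubled ranks are integers even with midrank ties, so the
    # distribution is a convolution over integer support.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1)  # index k+1 = P(2*W = k) * 2^n
    dist[1] <- 1
    for (rr in r2) {
      shifted <- c(rep(0, rr), dist[seq_len(total + 1 - rr)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Volume error statistics against ground truth
#'
#' Cohort-level deviation of predicted from true muscle volumes: the mean
#' signed percentage error of the cohort means, the mean squared
#' difference (cm^6, a squared-volume quantity) and its root (RMSE, cm^3).
#'
#' @param pred,truth Paired volume vectors (cm^3).
#' @return List with `mean_signed_pct`, `mean_squared_diff`, `rmse`.
#' @export
volume_error_stats <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("lengths differ", call. = FALSE)
  msd <- mean((pred - truth)^2)
  list(mean_signed_pct = (mean(pred) - mean(truth)) / mean(truth) * 100,
       mean_squared_diff = msd,
       rmse = sqrt(msd))
}

#' Bootstrap confidence interval for a median
#'
#' Nonparametric percentile bootstrap, seeded.
#'
#' @param x Numeric vector.
#' @param n_boot Number of resamples (default 10000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Named vector `c(median, lower, upper)`.
#' @export
median_ci <- function(x, n_boot = 10000, conf = 0.95, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  meds <- vapply(seq_len(n_boot),
                 function(i) stats::median(sample(x, replace = TRUE)),
                 numeric(1))
  a <- (1 - conf) / 2
  c(median = stats::median(x),
    lower = unname(stats::quantile(meds, a)),
    upper = unname(stats::quantile(meds, 1 - a)))
}

#' Patient-level cross-validation folds
#'
#' Shuffles case ids with the given seed and partitions them into `k`
#' folds (larger folds first when `n %% k != 0`). Each case appears in
#' exactly one test set; the fold's training set is its complement.
#'
#' @param case_ids Character vector of case identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` fold splits, each `list(fold, train_ids, test_ids)`.
#' @export
make_folds <- function(case_ids, k = 5, seed = 1) {
  n <- length(case_ids)
  if (n < k) stop("fewer cases than folds", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  shuffled <- sample(case_ids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  lapply(seq_len(k), function(i) {
    test <- shuffled[starts[i]:stops[i]]
    list(fold = i, train_ids = setdiff(case_ids, test), test_ids = test)
  })
}
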