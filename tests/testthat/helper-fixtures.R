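# Shared fixtures, all generated in code.

# quick binary mask on an isotropic-ish grid
mk_mask <- function(arr, spacing = c(1, 1, 1), case_id = "t") {
  binary_mask(arr, spacing = spacing, case_id = case_id)
}

# seeded random mask of given dims and foreground probability
random_mask <- function(dims, p = 0.2, spacing = c(1, 1, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk_mask(array(stats::runif(prod(dims)) < p, dims), spacing = spacing)
}

# small, fast phantom configuration for tests that need full cases
tiny_phantom_params <- function(deform_amplitude_mm = 1.5, ...) {
  phantom_params(shape = c(32, 32, 10), spacing = c(2, 2, 5),
                 tube_radius_mm = 6, tube_offset_mm = 12,
                 deform_amplitude_mm = deform_amplitude_mm, ...)
}

# brute-force in-plane city-block dilation (independent oracle)
brute_dilate <- function(vox, r) {
  d <- dim(vox)
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    sl <- vox[, , z]
    res <- matrix(FALSE, d[1], d[2])
    idx <- which(sl, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
        if (any(abs(idx[, 1] - i) + abs(idx[, 2] - j) <= r)) res[i, j] <- TRUE
      }
    }
    out[, , z] <- res
  }
  out
}

# brute-force exact two-sided signed-rank p by enumerating all sign vectors
brute_wilcoxon_p <- function(xs, ys) {
  d <- xs - ys
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
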