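test_that("strict-majority voting matches per-voxel brute-force counting", {
  set.seed(314)
  for (rep in 1:10) {
    n <- sample(c(3, 4, 5, 6), 1)
    masks <- lapply(seq_len(n), function(i) random_mask(c(8, 8, 8), 0.4))
    fused <- majority_vote(masks)
    votes <- Reduce(`+`, lapply(masks, function(m) m$voxels * 1L))
    expect_identical(fused$voxels, votes > n / 2)
    # containment between intersection and union
    un <- Reduce(`|`, lapply(masks, `[[`, "voxels"))
    inter <- Reduce(`&`, lapply(masks, `[[`, "voxels"))
    expect_true(all(un[fused$voxels]))
    expect_true(all(fused$voxels[inter]))
    # permutation invariance
    expect_identical(majority_vote(rev(masks))$voxels, fused$voxels)
  }
})

test_that("voting threshold is strict: 3 of 5 in, 2 of 5 (and 2 of 4) out", {
  one <- function(on) {
    v <- array(FALSE, c(2, 2, 3)); if (on) v[1, 1, 1] <- TRUE
    mk_mask(v)
  }
  v3 <- majority_vote(c(replicate(3, one(TRUE), simplify = FALSE),
                        replicate(2, one(FALSE), simplify = FALSE)))
  expect_true(v3$voxels[1, 1, 1])
  v2 <- majority_vote(c(replicate(2, one(TRUE), simplify = FALSE),
                        replicate(3, one(FALSE), simplify = FALSE)))
  expect_false(v2$voxels[1, 1, 1])
  # even split excluded under the strict rule
  v22 <- majority_vote(c(replicate(2, one(TRUE), simplify = FALSE),
                         replicate(2, one(FALSE), simplify = FALSE)))
  expect_false(v22$voxels[1, 1, 1])
  # vote of one is the identity
  expect_true(majority_vote(list(one(TRUE)))$voxels[1, 1, 1])
})

test_that("atlas selection keeps the k lowest energies with stable tie-break", {
  mk_outcome <- function(e, id, ok = TRUE) {
    structure(list(final_energy = e, case_id = id, success = ok,
                   warped_mask = random_mask(c(4, 4, 3), 0.3)),
              class = "registration_outcome")
  }
  outs <- list(mk_outcome(3, "c"), mk_outcome(1, "a"), mk_outcome(5, "g"),
               mk_outcome(2, "b"), mk_outcome(4, "f"), mk_outcome(2.5, "d"),
               mk_outcome(6, "h"))
  sel <- rank_and_select(outs, k = 5)
  expect_equal(vapply(sel, `[[`, character(1), "case_id"),
               c("a", "b", "d", "c", "f"))
  # fewer than k: all returned, sorted
  sel3 <- rank_and_select(outs[1:3], k = 5)
  expect_equal(vapply(sel3, `[[`, character(1), "case_id"), c("a", "c", "g"))
  # equal energies: ordered by case id
  ties <- list(mk_outcome(1, "z"), mk_outcome(1, "m"), mk_outcome(1, "a"))
  expect_equal(vapply(rank_and_select(ties, 2), `[[`, character(1), "case_id"),
               c("a", "m"))
  # failures are excluded; nothing left is an error
  mixed <- list(mk_outcome(1, "bad", ok = FALSE), mk_outcome(9, "ok"))
  expect_equal(rank_and_select(mixed, 5)[[1]]$case_id, "ok")
  expect_error(rank_and_select(list(mk_outcome(1, "x", ok = FALSE))),
               "no successful")
})

test_that("energies and fusion are invariant to atlas processing order", {
  p <- tiny_phantom_params()
  t <- generate_case(p, 50, "t")
  pool <- lapply(1:3, function(i) {
    cs <- generate_case(p, 50 + i, sprintf("p%d", i))
    atlas(cs$image, cs$mask)
  })
  cfg_a <- affine_config(pyramid = c(2, 1), iterations = 25)
  m1 <- mas_segment(t$image, pool, cfg_a, bspline_cfg = NULL, k = 2, seed = 3)
  m2 <- mas_segment(t$image, rev(pool), cfg_a, bspline_cfg = NULL, k = 2,
                    seed = 3)
  e1 <- attr(m1, "energies"); e2 <- attr(m2, "energies")
  expect_equal(e1[sort(names(e1))], e2[sort(names(e2))])
  expect_identical(attr(m1, "selected"), attr(m2, "selected"))
  expect_identical(m1$voxels, m2$voxels)
})

test_that("a single self-atlas reduces multi-atlas segmentation to its own mask", {
  p <- tiny_phantom_params()
  cs <- generate_case(p, 3)
  cfg_a <- affine_config(pyramid = c(2, 1), iterations = 30)
  out <- mas_segment(cs$image, list(atlas(cs$image, cs$mask)),
                     affine_cfg = cfg_a, bspline_cfg = NULL, k = 5, seed = 1)
  expect_gte(dsc(out, cs$mask), 0.99)
  expect_equal(attr(out, "selected"), cs$image$case_id)
  expect_length(attr(out, "energies"), 1L)
})
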