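# Multi-atlas segmentation: register every atlas to the target, rank the
# fits by minimized energy, keep the five best, and fuse their propagated
# labels by strict-majority voting.

#' Select the best atlas registrations by minimized energy
#'
#' Discards failed registrations, sorts the rest ascending by
#' `final_energy` (ties broken deterministically by `case_id`) and returns
#' the best `min(k, available)`.
#'
#' @param outcomes List of [register_pair()] outcomes.
#' @param k Number of atlases to keep (default 5, the usual fusion count).
#' @return Sorted list of the selected outcomes.
#' @export
rank_and_select <- function(outcomes, k = 5) {
  ok <- Filter(function(o) isTRUE(o$success) && is.finite(o$final_energy),
               outcomes)
  if (length(ok) == 0)
    stop("no successful registrations to select from", call. = FALSE)
  energies <- vapply(ok, function(o) o$final_energy, numeric(1))
  ids <- vapply(ok, function(o) o$case_id, character(1))
  ord <- order(energies, ids)
  ok[ord[seq_len(min(k, length(ok)))]]
}

#' Strict-majority label fusion
#'
#' Sums the binary votes of `n` propagated masks; a voxel is foreground iff
#' it is present in strictly more than half of them (for `n = 5` that means
#' at least 3 votes; an even split on even `n` is excluded).
#'
#' @param masks Non-empty list of [binary_mask()] objects on one grid.
#' @return The fused [binary_mask()].
#' @export
majority_vote <- function(masks) {
  if (length(masks) == 0) stop("no masks to vote on", call. = FALSE)
  for (m in masks) stopifnot(inherits(m, "binary_mask"))
  if (length(masks) > 1)
    for (m in masks[-1]) stop_if_grid_mismatch(masks[[1]], m, "vote masks")
  votes <- Reduce(`+`, lapply(masks, function(m) {
    v <- m$voxels; storage.mode(v) <- "integer"; v
  }))
  n <- length(masks)
  binary_mask(votes > n / 2, spacing = masks[[1]]$spacing,
              case_id = masks[[1]]$case_id, label = "bilateral")
}

#' Multi-atlas segmentation of a target volume
#'
#' Registers every atlas to the target (dual-stage, see [register_pair()]),
#' keeps the `k` registrations with the lowest minimized energy and fuses
#' their propagated masks by strict-majority vote.
#'
#' @param target Target [image_volume()].
#' @param atlases Non-empty list of [atlas()] objects.
#' @param affine_cfg,bspline_cfg Stage configurations.
#' @param k Number of atlases fused (default 5).
#' @param seed Base seed; each atlas registration derives its own seed
#'   deterministically from it and the atlas `case_id`, so results do not
#'   depend on atlas order.
#' @return The fused [binary_mask()], with attributes `energies` (named
#'   per-atlas energies) and `selected` (case ids fused).
#' @export
mas_segment <- function(target, atlases, affine_cfg = affine_config(),
                        bspline_cfg = bspline_config(), k = 5, seed = 1) {
  if (length(atlases) == 0) stop("need at least one atlas", call. = FALSE)
  ids <- vapply(atlases, function(a) a$case_id, character(1))
  outcomes <- lapply(seq_along(atlases), function(i) {
    # per-atlas seed from a stable hash of the case id, independent of order
    s <- (as.integer(seed) * 131L +
            sum(utf8ToInt(ids[i]) * seq_along(utf8ToInt(ids[i])))) %%
      2147483587L
    register_pair(target, atlases[[i]], affine_cfg, bspline_cfg, seed = s)
  })
  sel <- rank_and_select(outcomes, k)
  fused <- majority_vote(lapply(sel, function(o) o$warped_mask))
  fused$case_id <- target$case_id
  energies <- vapply(outcomes, function(o) o$final_energy, numeric(1))
  names(energies) <- ids
  attr(fused, "energies") <- energies
  attr(fused, "selected") <- vapply(sel, function(o) o$case_id, character(1))
  fused
}
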