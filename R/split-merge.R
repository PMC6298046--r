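#' Find split-peak candidate groups
#'
#' Peak matching occasionally assigns one ion source to several contiguous
#' m/z bins ("split peaks"). Candidates are maximal runs of adjacent peaks
#' whose consecutive m/z gaps all fall within the instrumental tolerance:
#' peaks `i` and `i + 1` are linked when
#' `mz[i + 1] - mz[i] <= tol_ppm * 1e-6 * mz[i + 1]` (or `<= tol_da` in
#' absolute units), and groups are the transitive closure of that relation.
#'
#' @param ds an `msi_dataset`.
#' @param tol_ppm tolerance in parts per million (default 10). Ignored when
#'   `tol_da` is given.
#' @param tol_da optional absolute tolerance in Da.
#' @return list of integer vectors (column indices, ascending m/z), each of
#'   length >= 2; empty list when nothing is contiguous.
#' @export
find_split_candidates <- function(ds, tol_ppm = 10, tol_da = NULL) {
  mz <- ds$mz
  if (length(mz) < 2L) return(list())
  gaps <- diff(mz)
  if (is.null(tol_da)) {
    if (tol_ppm < 0) stop("tol_ppm must be >= 0", call. = FALSE)
    linked <- gaps <= tol_ppm * 1e-6 * mz[-1L]
  } else {
    if (tol_da < 0) stop("tol_da must be >= 0", call. = FALSE)
    linked <- gaps <= tol_da
  }
  if (!any(linked)) return(list())
  run_id <- cumsum(c(0L, !linked)) # consecutive linked peaks share a run
  runs <- split(seq_along(mz), run_id)
  unname(runs[lengths(runs) >= 2L])
}

#' Evaluate whether a candidate group should be merged
#'
#' A group of contiguous peaks is merged when three conditions hold on the
#' Otsu-binarized member images:
#'
#' 1. every pair of member signal masks overlaps at most `overlap_max`,
#'    where overlap is `|A & B| / min(|A|, |B|)` (split peaks occupy small
#'    or non-overlapping regions);
#' 2. at least one member image reaches oriented regularity
#'    `>= regularity_min` (some member looks like structured signal);
#' 3. the pixel-wise sum of the member images is at least as regular as the
#'    most regular member (merging must not degrade spatial structure).
#'
#' Members whose image is degenerate (constant / no signal) contribute
#' overlap 0 and regularity 0.
#'
#' @param ds an `msi_dataset`.
#' @param group integer vector of >= 2 column indices.
#' @param measure regularity measure (see [regularity()]).
#' @param overlap_max maximum pairwise mask overlap (default 0.5).
#' @param regularity_min minimum best-member regularity (default 0.5).
#' @return list with `merge` (logical decision), the three condition flags,
#'   `overlaps` (pairwise matrix), `member_regularity`, `merged_regularity`.
#' @export
evaluate_merge <- function(ds, group, measure = "spatial_chaos",
                           overlap_max = 0.5, regularity_min = 0.5) {
  group <- as.integer(group)
  if (length(group) < 2L) stop("a split group needs >= 2 peaks",
                               call. = FALSE)
  imgs <- lapply(group, function(k) image_values(ion_image(ds, k)))
  masks <- lapply(imgs, function(v) {
    tryCatch(v > otsu_threshold(v), error = function(e) NULL)
  })
  k <- length(group)
  ov <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- masks[[i]]; b <- masks[[j]]
    if (is.null(a) || is.null(b)) next
    den <- min(sum(a), sum(b))
    ov[i, j] <- ov[j, i] <- if (den == 0L) 0 else sum(a & b) / den
  }
  reg <- vapply(imgs, regularity, numeric(1), measure = measure,
                degenerate_zero = TRUE)
  merged_img <- Reduce(`+`, imgs)
  merged_reg <- regularity(merged_img, measure = measure,
                           degenerate_zero = TRUE)
  cond_overlap <- all(ov[upper.tri(ov)] <= overlap_max)
  cond_regular <- max(reg) >= regularity_min
  cond_improves <- merged_reg >= max(reg)
  list(merge = cond_overlap && cond_regular && cond_improves,
       cond_overlap = cond_overlap, cond_regular = cond_regular,
       cond_improves = cond_improves, overlaps = ov,
       member_regularity = reg, merged_regularity = merged_reg)
}

#' Merge plan
#'
#' Validated grouping of split-peak columns with the m/z each merged group
#' maps to (intensity-weighted mean of the member m/z values).
#'
#' @param ds an `msi_dataset`.
#' @param groups list of integer vectors (pairwise disjoint, each >= 2).
#' @param diagnostics optional list of per-group [evaluate_merge()] results.
#' @return An object of class `merge_plan` with `groups`, `merged_mz`,
#'   `diagnostics`.
#' @export
merge_plan <- function(ds, groups, diagnostics = NULL) {
  groups <- lapply(groups, as.integer)
  idx <- unlist(groups)
  if (anyDuplicated(idx)) stop("merge groups must be disjoint",
                               call. = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_peaks(ds))) {
    stop("merge group indices out of range", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) stop("each merge group needs >= 2 peaks",
                                      call. = FALSE)
  merged_mz <- vapply(groups, function(g) {
    w <- colSums(ds$intensities[, g, drop = FALSE])
    if (sum(w) == 0) mean(ds$mz[g]) else stats::weighted.mean(ds$mz[g], w)
  }, numeric(1))
  structure(list(groups = groups, merged_mz = merged_mz,
                 diagnostics = diagnostics),
            class = "merge_plan")
}

#' @export
print.merge_plan <- function(x, ...) {
  cat(sprintf("merge_plan: %d group(s), %d columns merged away\n",
              length(x$groups),
              sum(lengths(x$groups)) - length(x$groups)))
  invisible(x)
}

#' Apply a merge plan
#'
#' Replaces each group's columns by their pixel-wise sum at the group's
#' merged m/z. The grand total intensity of the matrix is conserved exactly
#' and the output m/z axis is re-sorted.
#'
#' @param ds an `msi_dataset`.
#' @param plan a `merge_plan` (e.g. from [merge_split_peaks()]); an empty
#'   plan returns the dataset unchanged.
#' @return A new `msi_dataset` with merged columns.
#' @export
apply_merge <- function(ds, plan) {
  if (!inherits(plan, "merge_plan")) stop("'plan' must be a merge_plan",
                                          call. = FALSE)
  if (!length(plan$groups)) return(ds)
  drop_idx <- unlist(plan$groups)
  if (max(drop_idx) > n_peaks(ds)) stop("plan is stale for this dataset",
                                        call. = FALSE)
  keep_idx <- setdiff(seq_len(n_peaks(ds)), drop_idx)
  merged_cols <- vapply(plan$groups, function(g) {
    rowSums(ds$intensities[, g, drop = FALSE])
  }, numeric(n_pixels(ds)))
  merged_ids <- vapply(plan$groups, function(g) {
    paste(ds$peak_ids[g], collapse = "+")
  }, character(1))
  intens <- cbind(ds$intensities[, keep_idx, drop = FALSE], merged_cols)
  mz <- c(ds$mz[keep_idx], plan$merged_mz)
  ids <- c(ds$peak_ids[keep_idx], merged_ids)
  ord <- order(mz)
  msi_dataset(intens[, ord, drop = FALSE], mz[ord], ds$shape, ids[ord])
}

#' Detect and merge split peaks
#'
#' End-to-end split-peak correction: find contiguous-m/z candidate groups,
#' evaluate each with [evaluate_merge()], merge the groups that pass, and
#' repeat (merging can create new adjacency) up to `max_passes` times or
#' until a fixed point. Should always run before any other filter, since
#' the other filters assume one column per ion source.
#'
#' @inheritParams find_split_candidates
#' @inheritParams evaluate_merge
#' @param max_passes maximum merge passes (default 3).
#' @return list with `dataset` (merged), `plan` (the first-pass
#'   `merge_plan`), `report` (data frame: one row per evaluated group) and
#'   `n_passes`.
#' @export
merge_split_peaks <- function(ds, tol_ppm = 10, tol_da = NULL,
                              measure = "spatial_chaos", overlap_max = 0.5,
                              regularity_min = 0.5, max_passes = 3L) {
  report <- list()
  first_plan <- NULL
  pass <- 0L
  repeat {
    pass <- pass + 1L
    cands <- find_split_candidates(ds, tol_ppm, tol_da)
    if (!length(cands)) break
    evals <- lapply(cands, evaluate_merge, ds = ds, measure = measure,
                    overlap_max = overlap_max,
                    regularity_min = regularity_min)
    decided <- vapply(evals, `[[`, logical(1), "merge")
    report[[pass]] <- data.frame(
      pass = pass,
      group = vapply(cands, function(g) paste(ds$peak_ids[g],
                                              collapse = "+"), character(1)),
      mz_min = vapply(cands, function(g) min(ds$mz[g]), numeric(1)),
      mz_max = vapply(cands, function(g) max(ds$mz[g]), numeric(1)),
      max_overlap = vapply(evals, function(e)
        if (length(e$overlaps) > 1) max(e$overlaps[upper.tri(e$overlaps)])
        else 0, numeric(1)),
      best_member_regularity = vapply(evals, function(e)
        max(e$member_regularity), numeric(1)),
      merged_regularity = vapply(evals, `[[`, numeric(1),
                                 "merged_regularity"),
      merged = decided,
      stringsAsFactors = FALSE
    )
    if (!any(decided)) break
    plan <- merge_plan(ds, cands[decided], evals[decided])
    if (is.null(first_plan)) first_plan <- plan
    ds <- apply_merge(ds, plan)
    if (pass >= max_passes) break
  }
  if (is.null(first_plan)) first_plan <- merge_plan(ds, list())
  list(dataset = ds, plan = first_plan,
       report = if (length(report)) do.call(rbind, report)
                else data.frame(),
       n_passes = pass)
}
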