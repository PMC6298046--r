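#' Filter result
#'
#' Common return type of all peak filters: one score per peak, the boolean
#' keep decision, and the full parameter record so a run can be audited and
#' reproduced. `keep` is always a deterministic function of the scores and
#' parameters.
#'
#' @param filter_name character name of the filter.
#' @param scores numeric vector, one per peak (meaning depends on the
#'   filter: similarity, component size, or adjusted p-value).
#' @param keep logical vector, same length.
#' @param params named list of the parameters used.
#' @param ds the filtered `msi_dataset` (peak ids and m/z are recorded).
#' @param extra optional named list of additional per-peak columns.
#' @return An object of class `filter_result`.
#' @export
filter_result <- function(filter_name, scores, keep, params, ds,
                          extra = NULL) {
  stopifnot(length(scores) == n_peaks(ds), length(keep) == n_peaks(ds))
  structure(list(filter = filter_name, scores = scores, keep = keep,
                 params = params, peak_ids = ds$peak_ids, mz = ds$mz,
                 extra = extra),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result [%s]: %d/%d peaks kept\n", x$filter,
              sum(x$keep), length(x$keep)))
  invisible(x)
}

#' Tabulate a filter result
#' @param x a `filter_result`.
#' @param ... unused.
#' @return data frame with peak id, m/z, score, keep and any extra columns.
#' @export
as.data.frame.filter_result <- function(x, ...) {
  df <- data.frame(peak_id = x$peak_ids, mz = x$mz, score = x$scores,
                   keep = x$keep, filter = x$filter,
                   stringsAsFactors = FALSE)
  if (!is.null(x$extra)) df <- cbind(df, as.data.frame(x$extra))
  df
}

#' Reference-image similarity filter
#'
#' Scores every peak by the similarity of its ion image to a reference
#' (a continuous reference image or a binary ROI mask) and keeps peaks
#' scoring strictly above the threshold. Matrix/solvent peaks whose
#' distribution is unrelated to the tissue shape score at or below 0 and
#' are removed at the default threshold of 0, while ions confined to small
#' sub-regions of the ROI stay weakly positive and are retained. Peaks with
#' a constant (typically all-zero) image carry no spatial information: they
#' score `-Inf` and are dropped.
#'
#' @param ds an `msi_dataset`.
#' @param ref reference: an `msi_image` or a `roi_mask` (converted to its
#'   0/1 indicator image for correlation measures).
#' @param measure similarity measure, see [similarity()] (default
#'   `"spearman"`).
#' @param threshold keep peaks with `score > threshold` (default 0).
#' @return A `filter_result` with the similarity scores.
#' @export
reference_filter <- function(ds, ref, measure = c("spearman", "pearson",
                                                  "ssim", "nmi"),
                             threshold = 0) {
  measure <- match.arg(measure)
  rv <- image_values(ref)
  if (!identical(dim(rv), as.integer(ds$shape)) &&
      !identical(dim(rv), c(ds$shape[1], ds$shape[2]))) {
    stop("reference dimensions do not match the dataset grid",
         call. = FALSE)
  }
  if (measure %in% c("spearman", "pearson") && stats::sd(as.vector(rv)) == 0) {
    stop("constant reference: correlation undefined (an all-ones ROI ",
         "cannot serve as a correlation reference)", call. = FALSE)
  }
  scores <- vapply(seq_len(n_peaks(ds)), function(k) {
    img <- ion_image(ds, k)
    tryCatch(similarity(img, ref, measure), error = function(e) -Inf)
  }, numeric(1))
  keep <- scores > threshold
  filter_result("reference_similarity", scores, keep,
                params = list(measure = measure, threshold = threshold,
                              reference = if (inherits(ref, "roi_mask"))
                                paste0("roi:", ref$origin)
                              else if (inherits(ref, "msi_image"))
                                ref$method else "matrix"),
                ds)
}

#' Connected-pixel-count filter
#'
#' Removes shot-noise peaks whose above-background signal never forms a
#' pixel cluster of meaningful size. Each ion image is binarized at its own
#' Otsu threshold ("higher than the background level" is a per-peak
#' notion), the 8-connected components of the signal mask are labeled, and
#' the peak is kept according to the aggressiveness level:
#'
#' * level 0 — some component intersecting the ROI has at least
#'   `min_pixels` pixels inside the ROI;
#' * level 1 — additionally, the largest ROI-intersecting component is at
#'   least as large as the largest component lying fully outside the ROI;
#' * level 2 — additionally, there are more signal pixels inside the ROI
#'   than outside it.
#'
#' The score is the largest ROI-restricted component size. Degenerate
#' (constant) ion images are dropped with score 0. Under an all-ones ROI
#' levels 1 and 2 reduce to level 0.
#'
#' @param ds an `msi_dataset`.
#' @param roi a `roi_mask`.
#' @param min_pixels minimum in-ROI connected cluster size (default 4,
#'   i.e. clusters smaller than the smallest meaningful sub-region are
#'   noise).
#' @param aggressive 0, 1 or 2.
#' @param connectivity 8 (default) or 4.
#' @return A `filter_result`; `extra$inside_pixels` / `extra$outside_pixels`
#'   give the signal-pixel split.
#' @export
count_filter <- function(ds, roi, min_pixels = 4L, aggressive = 0L,
                         connectivity = 8L) {
  if (!inherits(roi, "roi_mask")) stop("'roi' must be a roi_mask",
                                       call. = FALSE)
  if (!identical(dim(roi$mask), c(ds$shape[1], ds$shape[2]))) {
    stop("ROI dimensions do not match the dataset grid", call. = FALSE)
  }
  if (!any(roi$mask)) stop("empty ROI", call. = FALSE)
  min_pixels <- as.integer(min_pixels)
  if (min_pixels < 1L) stop("min_pixels must be >= 1", call. = FALSE)
  aggressive <- as.integer(aggressive)
  if (!aggressive %in% 0:2) stop("aggressive must be 0, 1 or 2",
                                 call. = FALSE)
  m <- roi$mask
  n <- n_peaks(ds)
  scores <- numeric(n)
  keep <- logical(n)
  inside <- integer(n)
  outside <- integer(n)
  for (k in seq_len(n)) {
    v <- image_values(ion_image(ds, k))
    mask <- tryCatch(v > otsu_threshold(v), error = function(e) NULL)
    if (is.null(mask) || !any(mask)) next # degenerate: dropped, score 0
    lab <- label_components(mask, connectivity)
    n_comp <- max(lab)
    sz_total <- tabulate(lab[lab > 0], nbins = n_comp)
    sz_in <- tabulate(lab[lab > 0 & m], nbins = n_comp)
    sz_out <- sz_total - sz_in
    intersecting <- sz_in > 0L
    scores[k] <- if (any(intersecting)) max(sz_in) else 0
    inside[k] <- sum(sz_in)
    outside[k] <- sum(sz_out)
    ok <- any(sz_in >= min_pixels)
    if (aggressive >= 1L && ok) {
      largest_in <- max(sz_total[intersecting])
      largest_out <- if (any(!intersecting)) max(sz_total[!intersecting])
                     else 0L
      ok <- largest_in >= largest_out
    }
    if (aggressive >= 2L && ok) ok <- inside[k] > outside[k]
    keep[k] <- ok
  }
  filter_result("pixel_count", scores, keep,
                params = list(min_pixels = min_pixels,
                              aggressive = aggressive,
                              connectivity = connectivity,
                              roi = roi$origin),
                ds,
                extra = list(inside_pixels = inside,
                             outside_pixels = outside))
}
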