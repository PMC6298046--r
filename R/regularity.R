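#' Scattered-pixel ratio
#'
#' Fraction of Otsu-thresholded signal pixels that do not belong to the
#' largest connected component. A single compact blob scores 0; isolated
#' shot-noise pixels score close to 1. The oriented regularity is
#' `1 - ratio` (higher = more regular).
#'
#' @param img an `msi_image` or matrix with at least two distinct values.
#' @param connectivity 8 (default) or 4.
#' @return A list of class `regularity_score` with `value` (oriented, in
#'   `[0, 1]`), `raw` (the scattered ratio) and `measure = "scatter_ratio"`.
#' @export
scatter_ratio <- function(img, connectivity = 8L) {
  mask <- otsu_mask(img)
  n_sig <- sum(mask)
  if (n_sig == 0L) stop("no signal pixels after Otsu binarization",
                        call. = FALSE)
  lab <- label_components(mask, connectivity)
  sizes <- component_sizes(lab)
  raw <- (n_sig - max(sizes)) / n_sig
  regularity_score(1 - raw, raw, "scatter_ratio")
}

#' Spatial chaos
#'
#' Multi-level isolation measure: the nonzero intensities are thresholded at
#' `n_levels` quantile levels; at each level the image is binarized
#' (`value > threshold`) and the fraction of signal pixels with no signal
#' neighbor (8-neighborhood by default) is computed. Chaos is the mean
#' fraction over the levels that retain at least one signal pixel; oriented
#' regularity is `1 - chaos`. This is a variant construction: the published
#' "measure of chaos" literature uses edge-detection internals that are not
#' reproduced here, but the orientation (lower chaos = more structure) is
#' the same.
#'
#' @param img an `msi_image` or matrix with at least two distinct values.
#' @param n_levels number of quantile thresholds (default 64).
#' @param connectivity 8 (default) or 4.
#' @return A `regularity_score` with `measure = "spatial_chaos"`.
#' @export
spatial_chaos <- function(img, n_levels = 64L, connectivity = 8L) {
  v <- image_values(img)
  if (length(unique(as.vector(v))) < 2L) {
    stop("constant image: spatial chaos undefined", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  nz <- v[v > 0]
  if (!length(nz)) stop("image has no positive values", call. = FALSE)
  thr <- stats::quantile(nz, probs = seq(0, 1, length.out = n_levels),
                         names = FALSE)
  fracs <- vapply(thr, function(t) {
    mask <- v >= t # >= so the top level keeps the maximal pixels
    n_sig <- sum(mask)
    if (n_sig == 0L) return(NA_real_)
    iso <- sum(mask & neighbor_counts(mask, connectivity) == 0)
    iso / n_sig
  }, numeric(1))
  fracs <- fracs[!is.na(fracs)]
  if (!length(fracs)) stop("no level retains signal pixels", call. = FALSE)
  chaos <- mean(fracs)
  regularity_score(1 - chaos, chaos, "spatial_chaos")
}

#' Gini index of an intensity image
#'
#' Concentration of the intensity distribution over pixels:
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, in `[0, 1)`. 0 means
#' perfectly uniform intensity; values near 1 mean the signal is
#' concentrated on few pixels. Used directly as the oriented regularity
#' (localized signal = regular). Scale-invariant.
#'
#' @param img an `msi_image`, matrix or numeric vector of non-negative
#'   values with a positive sum.
#' @return A `regularity_score` with `measure = "gini"`.
#' @export
gini_index <- function(img) {
  x <- if (is.numeric(img) && is.null(dim(img))) as.numeric(img)
       else as.numeric(image_values(img))
  if (any(x < 0)) stop("Gini index requires non-negative values",
                       call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("Gini index undefined for an all-zero image",
                   call. = FALSE)
  n <- length(x)
  xs <- sort(x)
  g <- (2 * sum(seq_len(n) * xs) - (n + 1) * s) / (n * s)
  regularity_score(g, g, "gini")
}

regularity_score <- function(value, raw, measure) {
  structure(list(value = value, raw = raw, measure = measure),
            class = "regularity_score")
}

#' @export
print.regularity_score <- function(x, ...) {
  cat(sprintf("%s: regularity %.4f (raw %.4f)\n", x$measure, x$value, x$raw))
  invisible(x)
}

#' Oriented spatial regularity of an image
#'
#' Dispatcher over the three regularity measures; returns the oriented
#' value in `[0, 1]` (higher = more spatially regular). Degenerate images
#' (constant, or no signal) score 0 when `degenerate_zero = TRUE` instead of
#' raising, which is the policy used during split-peak evaluation.
#'
#' @param img an `msi_image` or matrix.
#' @param measure one of `"scatter_ratio"`, `"spatial_chaos"`, `"gini"`.
#' @param degenerate_zero return 0 instead of erroring on degenerate input.
#' @param ... passed to the selected measure.
#' @return numeric oriented regularity.
#' @export
regularity <- function(img, measure = c("spatial_chaos", "scatter_ratio",
                                        "gini"),
                       degenerate_zero = FALSE, ...) {
  measure <- match.arg(measure)
  f <- switch(measure, scatter_ratio = scatter_ratio,
              spatial_chaos = spatial_chaos, gini = gini_index)
  if (degenerate_zero) {
    out <- tryCatch(f(img, ...), error = function(e) NULL)
    if (is.null(out)) return(0)
    return(out$value)
  }
  f(img, ...)$value
}
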