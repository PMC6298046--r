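#' Otsu threshold of an image
#'
#' Histogram threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. Candidate thresholds are the interior edges of
#' `n_bins` equal-width bins spanning `[min, max]` of the image; the classes
#' at a candidate `t` are `value <= t` (background) and `value > t` (signal).
#' The returned threshold is the first candidate attaining the maximum, so
#' the result is deterministic.
#'
#' @param img an `msi_image`, matrix or numeric vector.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold value; pixels strictly greater than it are signal.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- if (is.numeric(img) && is.null(dim(img))) as.numeric(img)
       else as.numeric(image_values(img))
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("need at least 2 pixels", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    stop("constant image: Otsu threshold undefined", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  edges <- rng[1] + (seq_len(n_bins - 1L) / n_bins) * (rng[2] - rng[1])
  # class membership per candidate via cumulative sums over sorted values
  vs <- sort(v)
  n <- length(vs)
  csum <- cumsum(vs)
  total <- csum[n]
  # number of values <= each candidate edge
  n0 <- findInterval(edges, vs)
  w0 <- n0 / n
  w1 <- 1 - w0
  s0 <- ifelse(n0 > 0L, csum[pmax(n0, 1L)], 0)
  s0[n0 == 0L] <- 0
  mu0 <- ifelse(n0 > 0L, s0 / n0, 0)
  mu1 <- ifelse(n0 < n, (total - s0) / (n - n0), 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[n0 == 0L | n0 == n] <- -Inf
  if (all(!is.finite(bcv))) {
    stop("degenerate histogram: Otsu threshold undefined", call. = FALSE)
  }
  edges[which.max(bcv)]
}

#' Binarize an image by its Otsu threshold
#'
#' @inheritParams otsu_threshold
#' @return logical matrix, `TRUE` where `value > otsu_threshold(img)`.
#' @export
otsu_mask <- function(img, n_bins = 256L) {
  v <- image_values(img)
  v > otsu_threshold(v, n_bins)
}
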