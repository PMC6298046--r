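#' Similarity between two images
#'
#' Scalar similarity between an ion image and a reference (another image or
#' a binary ROI mask). Four measures:
#'
#' * `pearson`, `spearman` — correlation of the flattened pixel vectors
#'   (in `[-1, 1]`); undefined for constant inputs.
#' * `ssim` — mean local structural similarity (Gaussian window, sigma 1.5,
#'   11 x 11 support; stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with
#'   `L` the dynamic range of the two images pooled).
#' * `nmi` — normalized mutual information `I(A;B) / sqrt(H(A) H(B))` on
#'   equal-width histograms (default 256 bins; a binary mask keeps its two
#'   natural levels), in `[0, 1]`.
#'
#' All four are symmetric in their arguments.
#'
#' @param a,b `msi_image`, `roi_mask` or matrix, same dimensions.
#' @param measure one of `"pearson"`, `"spearman"`, `"ssim"`, `"nmi"`.
#' @param n_bins histogram bins for `nmi`.
#' @return numeric similarity value.
#' @export
similarity <- function(a, b, measure = c("pearson", "spearman", "ssim",
                                         "nmi"),
                       n_bins = 256L) {
  measure <- match.arg(measure)
  va <- image_values(a)
  vb <- image_values(b)
  if (!identical(dim(va), dim(vb))) {
    stop("images have different dimensions", call. = FALSE)
  }
  switch(measure,
    pearson = ,
    spearman = {
      x <- as.vector(va); y <- as.vector(vb)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        stop("constant image: correlation undefined", call. = FALSE)
      }
      stats::cor(x, y, method = measure)
    },
    ssim = ssim(va, vb),
    nmi = {
      bins_a <- if (inherits(a, "roi_mask")) 2L else n_bins
      bins_b <- if (inherits(b, "roi_mask")) 2L else n_bins
      nmi(va, vb, bins_a, bins_b)
    }
  )
}

# Structural similarity index, mean over the local SSIM map.
ssim <- function(a, b, sigma = 1.5, half_width = 5L) {
  L <- diff(range(c(a, b)))
  if (L == 0) L <- 1  # two identical constant images: SSIM map is all ones
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  w <- gaussian_kernel_1d(sigma, half_width)
  mu_a <- conv_sep(a, w)
  mu_b <- conv_sep(b, w)
  s_aa <- conv_sep(a * a, w) - mu_a^2
  s_bb <- conv_sep(b * b, w) - mu_b^2
  s_ab <- conv_sep(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * s_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2)
  mean(num / den)
}

gaussian_kernel_1d <- function(sigma, half_width) {
  x <- seq.int(-half_width, half_width)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable 2-D convolution with reflect padding (weights always sum to 1).
conv_sep <- function(m, w) {
  t(conv_axis(t(conv_axis(m, w)), w))
}

# Convolve each column of m with kernel w, reflecting at the borders.
conv_axis <- function(m, w) {
  hw <- (length(w) - 1L) %/% 2L
  nr <- nrow(m)
  if (nr == 1L) return(m)
  # reflect indices (no edge repeat): rows hw+1..2 above, nr-1..nr-hw below
  idx_top <- rev(seq_len(hw) + 1L)
  idx_bot <- nr - seq_len(hw)
  idx_top <- pmin(pmax(idx_top, 1L), nr)
  idx_bot <- pmin(pmax(idx_bot, 1L), nr)
  mp <- rbind(m[idx_top, , drop = FALSE], m, m[idx_bot, , drop = FALSE])
  out <- matrix(0, nr, ncol(m))
  for (k in seq_along(w)) {
    out <- out + w[k] * mp[(k - 1L) + seq_len(nr), , drop = FALSE]
  }
  out
}

# Normalized mutual information on equal-width histograms.
nmi <- function(a, b, bins_a = 256L, bins_b = 256L) {
  ia <- bin_values(as.vector(a), bins_a)
  ib <- bin_values(as.vector(b), bins_b)
  na <- max(ia); nb <- max(ib)
  joint <- tabulate((ia - 1L) * nb + ib, nbins = na * nb)
  p <- joint / sum(joint)
  pa <- tabulate(ia, nbins = na) / length(ia)
  pb <- tabulate(ib, nbins = nb) / length(ib)
  ha <- entropy(pa)
  hb <- entropy(pb)
  if (ha == 0 || hb == 0) {
    stop("constant image: normalized mutual information undefined",
         call. = FALSE)
  }
  pij <- p[p > 0]
  # expected products of marginals aligned with the joint table layout
  pm <- as.vector(outer(pb, pa))  # index (ia-1)*nb + ib -> pa[ia]*pb[ib]
  mi <- sum(pij * log(pij / pm[p > 0]))
  max(0, min(1, mi / sqrt(ha * hb)))
}

bin_values <- function(x, n_bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  i <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  pmin(as.integer(i), as.integer(n_bins))
}

entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
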