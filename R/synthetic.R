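#' Synthetic MSI dataset with known ground truth
#'
#' Generates a peak-matched MSI dataset that emulates the signal classes a
#' spatial filter must separate:
#'
#' * `structured` — ions co-localized with a tissue-shaped ROI: a smooth
#'   positive random field supported on the ROI, plus additive Gaussian
#'   noise (clipped at 0);
#' * `off_tissue` — matrix/solvent-like ions supported on the ROI
#'   complement, built the same way;
#' * `noise` — shot-like scattered signal: each pixel lights up
#'   independently with probability `noise_density` (a Bernoulli pixel
#'   process, the grid analogue of a homogeneous Poisson process) with
#'   uniform intensity marks;
#' * split groups — a structured image whose positive pixels are randomly
#'   partitioned across 2-3 columns placed at contiguous m/z values a few
#'   ppm apart (peak-matching artifacts).
#'
#' The ROI is a smooth thresholded random field occupying 30-60% of the
#' grid. The m/z axis is drawn in [500, 900] with non-split peaks at least
#' 50 ppm apart. Everything is reproducible from `seed`.
#'
#' @param shape grid shape, at least `c(16, 16)` (default `c(64, 64)`).
#' @param n_structured,n_off_tissue,n_noise peak counts per class.
#' @param n_split_groups number of planted split-peak groups.
#' @param noise_sd additive noise standard deviation relative to the unit
#'   signal amplitude (default 0.05).
#' @param noise_density pixel firing probability of the shot-noise peaks
#'   (default 0.05).
#' @param seed integer seed.
#' @return list with `dataset` (an `msi_dataset`) and `truth`: `labels`
#'   (per-peak class), `roi_true` (a `roi_mask`), `split_groups` (list of
#'   column-index vectors), `split_images` (the source image of each
#'   group, as a matrix), `seed`.
#' @export
generate_synthetic <- function(shape = c(64L, 64L), n_structured = 20L,
                               n_off_tissue = 15L, n_noise = 15L,
                               n_split_groups = 0L, noise_sd = 0.05,
                               noise_density = 0.05, seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 16L)) stop("shape must be at least 16 x 16 for ",
                             "meaningful spatial structure", call. = FALSE)
  counts <- c(n_structured, n_off_tissue, n_noise, n_split_groups)
  if (any(counts < 0)) stop("peak counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0) stop("at least one peak is required", call. = FALSE)
  set.seed(as.integer(seed))
  nr <- shape[1]; nc <- shape[2]

  # tissue ROI: smoothed white noise thresholded at a random 40-70%
  # quantile, giving an ROI fraction of 30-60%
  field <- smooth_field(nr, nc, sigma = max(4, round(min(shape) / 6)))
  frac <- stats::runif(1, 0.30, 0.60)
  roi <- field > stats::quantile(field, 1 - frac, names = FALSE)
  roi_m <- roi_mask(roi, origin = "external")

  make_structured <- function(support) {
    f <- smooth_field(nr, nc, sigma = max(3, round(min(shape) / 10)))
    f <- (f - min(f)) / (max(f) - min(f))
    img <- ifelse(support, 0.2 + 0.8 * f, 0)
    img <- img + stats::rnorm(nr * nc, sd = noise_sd)
    pmax(img, 0)
  }
  make_noise <- function() {
    fire <- stats::runif(nr * nc) < noise_density
    img <- matrix(0, nr, nc)
    img[fire] <- stats::runif(sum(fire), 0.5, 1)
    img
  }

  cols <- list(); labels <- character(0); split_src <- list()
  for (i in seq_len(n_structured)) {
    cols <- c(cols, list(make_structured(roi)))
    labels <- c(labels, "structured")
  }
  for (i in seq_len(n_off_tissue)) {
    cols <- c(cols, list(make_structured(!roi)))
    labels <- c(labels, "off_tissue")
  }
  for (i in seq_len(n_noise)) {
    cols <- c(cols, list(make_noise()))
    labels <- c(labels, "noise")
  }
  split_members <- integer(0) # number of members per group, in order
  for (g in seq_len(n_split_groups)) {
    src <- make_structured(roi)
    k <- sample(2:3, 1)
    assign_to <- sample.int(k, nr * nc, replace = TRUE)
    for (j in seq_len(k)) {
      part <- matrix(0, nr, nc)
      sel <- assign_to == j
      part[sel] <- src[sel]
      cols <- c(cols, list(part))
      labels <- c(labels, "split_member")
    }
    split_src <- c(split_src, list(src))
    split_members <- c(split_members, k)
  }

  n_single <- n_structured + n_off_tissue + n_noise
  n_total_cols <- n_single + sum(split_members)
  # m/z axis: singles >= 50 ppm apart; split members a few ppm apart
  mz_single <- draw_spaced_mz(n_single + n_split_groups, 500, 900,
                              min_ppm = 50)
  mz <- numeric(n_total_cols)
  mz[seq_len(n_single)] <- mz_single[seq_len(n_single)]
  pos <- n_single
  split_groups <- list()
  base_idx <- n_single
  for (g in seq_len(n_split_groups)) {
    base <- mz_single[n_single + g]
    k <- split_members[g]
    offs <- cumsum(c(0, stats::runif(k - 1, 1e-6, 4e-6))) # gaps 1-4 ppm
    mz[pos + seq_len(k)] <- base * (1 + offs)
    split_groups[[g]] <- pos + seq_len(k)
    pos <- pos + k
  }

  ord <- order(mz)
  intens <- vapply(cols, function(m) as.vector(t(m)),
                   numeric(nr * nc))[, ord, drop = FALSE]
  labels <- labels[ord]
  inv <- match(seq_len(n_total_cols), ord) # old column -> new position
  split_groups <- lapply(split_groups, function(g) sort(inv[g]))
  ids <- paste0("P", seq_len(n_total_cols))
  ds <- msi_dataset(intens, mz[ord], shape, ids)
  list(dataset = ds,
       truth = list(labels = labels, roi_true = roi_m,
                    split_groups = split_groups, split_images = split_src,
                    seed = as.integer(seed)))
}

# Gaussian-smoothed white-noise field (separable smoothing, reflect pad).
smooth_field <- function(nr, nc, sigma) {
  w <- gaussian_kernel_1d(sigma, half_width = as.integer(ceiling(3 * sigma)))
  conv_sep(matrix(stats::rnorm(nr * nc), nr, nc), w)
}

# n m/z values in [lo, hi], consecutive gaps at least min_ppm.
draw_spaced_mz <- function(n, lo, hi, min_ppm) {
  if (n == 0L) return(numeric(0))
  repeat {
    mz <- sort(stats::runif(n, lo, hi))
    if (n < 2L || all(diff(mz) > min_ppm * 1e-6 * mz[-1L])) return(mz)
  }
}
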