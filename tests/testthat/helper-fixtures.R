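# Shared fixture builders. Everything is generated in code; no data files.

# dataset with random positive intensities
random_dataset <- function(n_pix = 20L, n_peaks = 6L, shape = NULL,
                           seed = 1L) {
  set.seed(seed)
  if (is.null(shape)) shape <- c(n_pix %/% 4L, 4L)
  stopifnot(prod(shape) == n_pix)
  msi_dataset(matrix(runif(n_pix * n_peaks), n_pix, n_peaks),
              mz = sort(500 + runif(n_peaks) * 400), shape = shape)
}

# solid rectangular blob of `value` on a zero background
blob_image <- function(nr = 10L, nc = 10L, rows = 3:5, cols = 3:5,
                       value = 10) {
  m <- matrix(0, nr, nc)
  m[rows, cols] <- value
  m
}

# salt-and-pepper shot noise image
noise_image <- function(nr = 32L, nc = 32L, density = 0.05, seed = 1L) {
  set.seed(seed)
  m <- matrix(0, nr, nc)
  fire <- runif(nr * nc) < density
  m[fire] <- runif(sum(fire), 0.5, 1)
  m
}

# dataset whose columns are the given image matrices
dataset_from_images <- function(..., mz = NULL) {
  imgs <- list(...)
  shape <- dim(imgs[[1]])
  cols <- vapply(imgs, function(m) as.vector(t(m)), numeric(prod(shape)))
  if (is.null(mz)) mz <- 500 + seq_along(imgs)
  msi_dataset(cols, mz = mz, shape = shape)
}

# brute-force flood fill labeling, the oracle for label_components
flood_fill_labels <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# exhaustive between-class-variance Otsu oracle on the same bin-edge grid
otsu_oracle <- function(v, n_bins = 256L) {
  rng <- range(v)
  edges <- rng[1] + (seq_len(n_bins - 1L) / n_bins) * (rng[2] - rng[1])
  best <- -Inf; best_t <- NA_real_
  for (t in edges) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# do two label matrices define the same partition of foreground pixels?
same_partition <- function(a, b) {
  fa <- a[a > 0]; fb <- b[b > 0]
  identical(a > 0, b > 0) &&
    !is.na(suppressWarnings(max(table(fa, fb) > 0))) &&
    all(rowSums(table(fa, fb) > 0) == 1) &&
    all(colSums(table(fa, fb) > 0) == 1)
}
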