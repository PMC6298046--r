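#' MSI peak-matched dataset
#'
#' Container for a peak-matched mass spectrometry imaging dataset: a
#' pixel-by-peak intensity matrix together with the m/z of each matched peak
#' and the shape of the rectangular pixel grid. Pixels are stored in
#' row-major order: pixel index `p` corresponds to grid position
#' `row = (p - 1) %/% n_cols + 1`, `col = (p - 1) %% n_cols + 1`.
#'
#' @param intensities numeric matrix, one row per pixel (row-major grid
#'   order), one column per matched peak. Must be non-negative and finite.
#' @param mz numeric vector of peak m/z values, strictly increasing, one per
#'   column of `intensities`.
#' @param shape integer vector `c(n_rows, n_cols)` of the pixel grid;
#'   `prod(shape)` must equal `nrow(intensities)`.
#' @param peak_ids optional character vector of stable per-peak identifiers;
#'   defaults to `"P<k>"`.
#'
#' @return An object of class `msi_dataset` with elements `intensities`,
#'   `mz`, `shape`, `peak_ids`.
#' @examples
#' ds <- msi_dataset(matrix(1:12, nrow = 6, ncol = 2), mz = c(500, 600),
#'                   shape = c(2, 3))
#' n_peaks(ds)
#' @export
msi_dataset <- function(intensities, mz, shape, peak_ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  mz <- as.numeric(mz)
  shape <- as.integer(shape)
  if (is.null(peak_ids)) {
    peak_ids <- paste0("P", seq_along(mz))
  }
  ds <- structure(
    list(intensities = intensities, mz = mz, shape = shape,
         peak_ids = as.character(peak_ids)),
    class = "msi_dataset"
  )
  validate_msi_dataset(ds)
}

validate_msi_dataset <- function(ds) {
  x <- ds$intensities
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("'intensities' must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("intensities must be finite and non-missing", call. = FALSE)
  }
  if (any(x < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (length(ds$shape) != 2L || any(ds$shape < 1L)) {
    stop("'shape' must be two positive integers c(n_rows, n_cols)",
         call. = FALSE)
  }
  if (prod(ds$shape) != nrow(x)) {
    stop(sprintf("shape %dx%d does not match %d pixel rows",
                 ds$shape[1], ds$shape[2], nrow(x)), call. = FALSE)
  }
  if (length(ds$mz) != ncol(x)) {
    stop("length(mz) must equal the number of peak columns", call. = FALSE)
  }
  if (length(ds$mz) > 1L && any(diff(ds$mz) <= 0)) {
    stop("'mz' must be strictly increasing", call. = FALSE)
  }
  if (length(ds$peak_ids) != ncol(x)) {
    stop("length(peak_ids) must equal the number of peak columns",
         call. = FALSE)
  }
  ds
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("msi_dataset: %d x %d pixel grid (%d pixels), %d peaks\n",
              x$shape[1], x$shape[2], nrow(x$intensities), length(x$mz)))
  if (length(x$mz)) {
    cat(sprintf("  m/z range: %.4f - %.4f\n", min(x$mz), max(x$mz)))
  }
  invisible(x)
}

#' Number of peaks / pixels in a dataset
#' @param ds an `msi_dataset`
#' @return integer count.
#' @export
n_peaks <- function(ds) length(ds$mz)

#' @rdname n_peaks
#' @export
n_pixels <- function(ds) nrow(ds$intensities)

#' Subset the peaks of a dataset
#'
#' @param ds an `msi_dataset`
#' @param keep logical or integer vector selecting peak columns.
#' @return An `msi_dataset` with the selected columns.
#' @export
subset_peaks <- function(ds, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  msi_dataset(ds$intensities[, idx, drop = FALSE], ds$mz[idx], ds$shape,
              ds$peak_ids[idx])
}

#' Single-channel MSI image
#'
#' A real-valued image on the dataset's pixel grid. Used for ion images,
#' reference images and covariates. `values` is an `n_rows x n_cols` matrix.
#'
#' @param values numeric matrix of pixel values; must be finite.
#' @param mz optional m/z of the source peak.
#' @param id optional source peak identifier.
#' @param method optional label of how the image was built (e.g. `"sum"`,
#'   `"mean"`, `"median"`, `"pca1"`, `"external"`).
#' @return An object of class `msi_image`.
#' @export
msi_image <- function(values, mz = NA_real_, id = NA_character_,
                      method = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("image values must be finite", call. = FALSE)
  }
  structure(list(values = values, mz = mz, id = id, method = method),
            class = "msi_image")
}

#' @export
print.msi_image <- function(x, ...) {
  cat(sprintf("msi_image: %d x %d", nrow(x$values), ncol(x$values)))
  if (!is.na(x$mz)) cat(sprintf(", m/z %.4f", x$mz))
  if (!is.na(x$method)) cat(sprintf(" [%s]", x$method))
  cat("\n")
  invisible(x)
}

# Accept either an msi_image/roi_mask or a bare matrix wherever an image is
# expected; returns the numeric value matrix.
image_values <- function(img) {
  if (inherits(img, "msi_image")) return(img$values)
  if (inherits(img, "roi_mask")) {
    v <- img$mask * 1.0
    return(v)
  }
  if (is.matrix(img)) return(img)
  stop("expected an msi_image, roi_mask or matrix", call. = FALSE)
}

#' Extract one peak's ion image
#'
#' Reshapes a peak column onto the 2-D pixel grid (row-major). The inverse
#' operation is [flatten_image()].
#'
#' @param ds an `msi_dataset`
#' @param peak peak column index (1-based) or a peak id string.
#' @return An `msi_image` whose `values[r, c]` equals the intensity of pixel
#'   `(r - 1) * n_cols + c`.
#' @export
ion_image <- function(ds, peak) {
  if (is.character(peak)) {
    peak <- match(peak, ds$peak_ids)
    if (is.na(peak)) stop("unknown peak id", call. = FALSE)
  }
  peak <- as.integer(peak)
  if (peak < 1L || peak > n_peaks(ds)) {
    stop(sprintf("peak index %d out of range [1, %d]", peak, n_peaks(ds)),
         call. = FALSE)
  }
  v <- matrix(ds$intensities[, peak], nrow = ds$shape[1], ncol = ds$shape[2],
              byrow = TRUE)
  msi_image(v, mz = ds$mz[peak], id = ds$peak_ids[peak])
}

#' Flatten an image back to a pixel vector
#'
#' Row-major inverse of [ion_image()]: `flatten_image(ion_image(ds, k))`
#' equals `ds$intensities[, k]` exactly.
#'
#' @param img an `msi_image`, `roi_mask` or matrix.
#' @return numeric (or logical, for masks) vector in row-major pixel order.
#' @export
flatten_image <- function(img) {
  if (inherits(img, "roi_mask")) return(as.vector(t(img$mask)))
  as.vector(t(image_values(img)))
}

#' Build a reference image from the full peak set
#'
#' Summarizes all peak intensities into a single per-pixel statistic: the
#' sum, mean or median across peaks, or the scores of the first principal
#' component of the (column-centered) pixel-by-peak matrix. The PC sign is
#' fixed so the scores correlate non-negatively with the per-pixel sum,
#' making the reference reproducible.
#'
#' @param ds an `msi_dataset`
#' @param method one of `"sum"`, `"mean"`, `"median"`, `"pca1"`.
#' @return An `msi_image` with the chosen `method` recorded.
#' @export
make_reference <- function(ds, method = c("sum", "mean", "median", "pca1")) {
  method <- match.arg(method)
  x <- ds$intensities
  if (ncol(x) == 0L) stop("dataset has no peaks", call. = FALSE)
  v <- switch(method,
    sum = rowSums(x),
    mean = rowMeans(x),
    median = apply(x, 1L, stats::median),
    pca1 = {
      if (ncol(x) < 2L) stop("pca1 needs at least 2 peaks", call. = FALSE)
      xc <- sweep(x, 2L, colMeans(x))
      if (all(abs(xc) < .Machine$double.eps * 100)) {
        stop("pca1 undefined for constant data", call. = FALSE)
      }
      sc <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, 1L]
      tic <- rowSums(x)
      if (stats::sd(tic) > 0 && stats::cor(sc, tic) < 0) sc <- -sc
      sc
    }
  )
  msi_image(matrix(v, nrow = ds$shape[1], ncol = ds$shape[2], byrow = TRUE),
            method = method)
}

#' Per-pixel TIC normalization
#'
#' Divides every pixel row by its total ion count (pixels with zero TIC
#' are left at zero). The filters operate on raw matched intensities by
#' default; TIC scaling is offered for instruments with strong per-pixel
#' sensitivity drift. Note that it distorts the all-peak sum reference
#' (which becomes constant on non-empty pixels), so ROI detection should
#' run before normalization or use k-means.
#'
#' @param ds an `msi_dataset`
#' @return A TIC-normalized `msi_dataset`.
#' @export
normalize_tic <- function(ds) {
  tic <- rowSums(ds$intensities)
  scale <- ifelse(tic > 0, 1 / tic, 0)
  msi_dataset(ds$intensities * scale, ds$mz, ds$shape, ds$peak_ids)
}

#' Total ion count image
#'
#' Per-pixel sum of all peak intensities, identical to
#' `make_reference(ds, "sum")`. Exposed by name because it is the canonical
#' covariate for the spatial-randomness filter.
#'
#' @param ds an `msi_dataset`
#' @return An `msi_image` with `method = "sum"`.
#' @export
tic_image <- function(ds) make_reference(ds, "sum")
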