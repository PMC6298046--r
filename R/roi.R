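#' Region-of-interest mask
#'
#' Binary mask on the pixel grid marking the expected signal source (e.g.
#' the tissue section). Created by [detect_roi()], [all_ones_roi()] or
#' directly from an external pre-registered raster.
#'
#' @param mask logical matrix.
#' @param origin one of `"otsu"`, `"kmeans"`, `"external"`, `"all_ones"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, origin = c("external", "otsu", "kmeans",
                                      "all_ones")) {
  origin <- match.arg(origin)
  if (!is.matrix(mask)) stop("'mask' must be a matrix", call. = FALSE)
  mask <- mask != 0
  if (!any(mask) && origin != "all_ones") {
    stop("ROI mask has no TRUE pixel", call. = FALSE)
  }
  structure(list(mask = mask, origin = origin), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask [%s]: %d x %d, %d/%d pixels in ROI\n", x$origin,
              nrow(x$mask), ncol(x$mask), sum(x$mask), length(x$mask)))
  invisible(x)
}

#' All-ones ROI
#'
#' The degenerate ROI covering every pixel, for datasets without off-tissue
#' regions. Under this ROI the count filter's aggressiveness levels all
#' reduce to level 0 (there are no outside-ROI pixels). It cannot serve as a
#' correlation reference (a constant image has no spatial contrast).
#'
#' @param shape `c(n_rows, n_cols)`.
#' @return A `roi_mask` with `origin = "all_ones"`.
#' @export
all_ones_roi <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) {
    stop("'shape' must be two positive integers", call. = FALSE)
  }
  roi_mask(matrix(TRUE, shape[1], shape[2]), origin = "all_ones")
}

#' Detect the tissue ROI of a dataset
#'
#' Two detection routes: Otsu-threshold a reference image (default: the
#' per-pixel sum of all peaks), or 2-means clustering of the pixel intensity
#' vectors with the ROI taken as the cluster of higher mean total ion count.
#' The k-means route uses a fixed seed so the mask is reproducible.
#'
#' @param ds an `msi_dataset`.
#' @param method `"otsu"` or `"kmeans"`.
#' @param reference optional `msi_image` used by the Otsu route; defaults to
#'   `make_reference(ds, "sum")`.
#' @param seed,nstart k-means initialization controls.
#' @return A `roi_mask` with the detection route recorded as its origin.
#' @export
detect_roi <- function(ds, method = c("otsu", "kmeans"), reference = NULL,
                       seed = 0L, nstart = 10L) {
  method <- match.arg(method)
  if (method == "otsu") {
    if (is.null(reference)) reference <- make_reference(ds, "sum")
    v <- image_values(reference)
    thr <- otsu_threshold(v)
    return(roi_mask(v > thr, origin = "otsu"))
  }
  x <- ds$intensities
  if (all(abs(sweep(x, 2L, x[1L, ], "-")) < .Machine$double.eps * 100)) {
    stop("constant dataset: k-means ROI undefined", call. = FALSE)
  }
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  fit <- stats::kmeans(x, centers = 2L, nstart = nstart, iter.max = 50L)
  tic <- rowSums(x)
  roi_cluster <- which.max(tapply(tic, fit$cluster, mean))
  mask_vec <- fit$cluster == as.integer(names(roi_cluster))
  roi_mask(matrix(mask_vec, ds$shape[1], ds$shape[2], byrow = TRUE),
           origin = "kmeans")
}

# save/restore .Random.seed so detect_roi does not disturb the caller's RNG
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
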