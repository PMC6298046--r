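#' Point pattern from signal pixels
#'
#' Treats the `TRUE` pixels of a binary mask as a 2-D point pattern (pixel
#' centers, in pixel units) observed in the rectangular grid window. This
#' is the object the complete-spatial-randomness tests operate on.
#'
#' A pattern can also be built from arbitrary (continuous) coordinates by
#' passing a numeric two-column matrix plus an explicit `window`; this is
#' how simulated Poisson patterns are represented.
#'
#' @param mask logical matrix or `roi_mask` (signal pixels become points),
#'   or a numeric n x 2 coordinate matrix (then `window` is required).
#' @param window `c(height, width)` of the observation rectangle; only
#'   used (and required) for coordinate input.
#' @return list of class `point_pattern` with `points` (n x 2 matrix of
#'   (row, col)), `window` `c(n_rows, n_cols)` and `n`.
#' @export
point_pattern <- function(mask, window = NULL) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  if (!is.matrix(mask)) stop("'mask' must be a matrix", call. = FALSE)
  if (is.logical(mask) || all(mask %in% c(0, 1))) {
    mask <- mask != 0
    pts <- which(mask, arr.ind = TRUE)
    window <- dim(mask)
  } else {
    if (ncol(mask) != 2L || is.null(window)) {
      stop("coordinate input needs an n x 2 matrix and a 'window'",
           call. = FALSE)
    }
    pts <- mask
    window <- as.numeric(window)
  }
  if (nrow(pts) < 1L) stop("point pattern needs at least one point",
                           call. = FALSE)
  structure(list(points = unname(pts), window = window, n = nrow(pts)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points in a %d x %d window\n", x$n,
              x$window[1], x$window[2]))
  invisible(x)
}

# Nearest-neighbour distance of each point (Euclidean, optionally toroidal).
nn_distances <- function(pts, window = NULL, toroidal = FALSE,
                         chunk = 512L) {
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  out <- numeric(n)
  for (start in seq.int(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    dr <- outer(pts[idx, 1L], pts[, 1L], "-")
    dc <- outer(pts[idx, 2L], pts[, 2L], "-")
    if (toroidal) {
      dr <- abs(dr); dc <- abs(dc)
      dr <- pmin(dr, window[1] - dr)
      dc <- pmin(dc, window[2] - dc)
    }
    d2 <- dr * dr + dc * dc
    d2[cbind(seq_along(idx), idx)] <- Inf # self-distance
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Clark-Evans test of complete spatial randomness
#'
#' Nearest-neighbour index `R = dbar_obs / dbar_exp`, the ratio of the mean
#' observed nearest-neighbour distance to its expectation `1 / (2 sqrt(l))`
#' under a homogeneous Poisson process of intensity `l = n / area`. `R < 1`
#' indicates aggregation, `R > 1` regularity. The default alternative is
#' one-sided toward aggregation (`p = P(Z <= z)`), since informative ion
#' signals cluster on tissue structures.
#'
#' Edge handling: `"donnelly"` (default) applies the Donnelly (1978)
#' boundary correction to the null mean and variance of `dbar_obs`,
#' `"none"` uses the unbounded-plane moments (conservative toward
#' aggregation, because border points inflate observed distances), and
#' `"toroidal"` measures distances on the torus (no edges). The reported
#' `statistic` is always the uncorrected index `R`.
#'
#' @param pp a `point_pattern` (or logical mask, converted automatically).
#' @param correction `"donnelly"`, `"none"` or `"toroidal"`.
#' @param alternative `"clustered"` (one-sided, default) or `"two.sided"`.
#' @return list of class `csr_test` with `statistic` (R), `z`, `p`,
#'   `method`, `n`.
#' @export
clark_evans <- function(pp, correction = c("donnelly", "none", "toroidal"),
                        alternative = c("clustered", "two.sided")) {
  correction <- match.arg(correction)
  alternative <- match.arg(alternative)
  if (!inherits(pp, "point_pattern")) pp <- point_pattern(pp)
  n <- pp$n
  if (n < 2L) stop("Clark-Evans test needs at least 2 points",
                   call. = FALSE)
  area <- prod(pp$window)
  if (area <= 0) stop("window has zero area", call. = FALSE)
  perim <- 2 * sum(pp$window)
  lambda <- n / area
  d_obs <- mean(nn_distances(pp$points, pp$window,
                             toroidal = correction == "toroidal"))
  d_exp_plane <- 0.5 / sqrt(lambda)
  R <- d_obs / d_exp_plane
  if (correction == "donnelly") {
    mu <- d_exp_plane + (0.0514 + 0.041 / sqrt(n)) * perim / n
    v <- 0.070 * area / n^2 + 0.037 * perim * sqrt(area / n^5)
  } else {
    mu <- d_exp_plane
    v <- (0.26136 / sqrt(n * lambda))^2
  }
  z <- (d_obs - mu) / sqrt(v)
  p <- if (alternative == "clustered") stats::pnorm(z)
       else 2 * stats::pnorm(-abs(z))
  structure(list(statistic = R, z = z, p = min(1, p),
                 method = "clark_evans", correction = correction,
                 alternative = alternative, n = n),
            class = "csr_test")
}

#' @export
print.csr_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, p = %.4g (n = %d)\n", x$method,
              x$statistic, x$p, x$n))
  invisible(x)
}

# Survival function of the Kolmogorov distribution, P(sqrt(n) D > t).
kolmogorov_sf <- function(t, terms = 100L) {
  if (t <= 0) return(1)
  k <- seq_len(terms)
  s <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, s))
}

#' Kolmogorov-Smirnov CSR test against a covariate image
#'
#' Under complete spatial randomness a point pattern samples pixels
#' uniformly, so the covariate values observed at the points are
#' distributed like the covariate over the whole window. The test compares
#' the empirical CDF of the covariate at the pattern points with the
#' window-wide covariate CDF: `D = sup |F_points(v) - F_window(v)|`, with
#' an asymptotic one-sample Kolmogorov p-value. Because the `n` pattern
#' pixels are themselves part of the `N` window pixels, the difference of
#' the two CDFs has variance `(1 - n/N) F (1 - F) / n`, not
#' `F (1 - F) / n`; the p-value therefore uses the effective sample size
#' `n / (1 - n/N)` (the finite-population analogue of the two-sample
#' reduction), which keeps the test calibrated for any sampling fraction.
#' A peak whose signal pixels sit where the covariate (typically the TIC
#' image) is high yields a large `D`.
#'
#' @param pp a `point_pattern` (or logical mask).
#' @param covariate `msi_image` or matrix matching the window dimensions;
#'   must be non-constant.
#' @return list of class `csr_test` with `statistic` (D in `[0, 1]`), `p`,
#'   `n`.
#' @export
ks_covariate <- function(pp, covariate) {
  if (!inherits(pp, "point_pattern")) pp <- point_pattern(pp)
  cv <- image_values(covariate)
  if (!identical(dim(cv), as.integer(pp$window))) {
    stop("covariate dimensions do not match the pattern window",
         call. = FALSE)
  }
  v_all <- as.vector(cv)
  if (min(v_all) == max(v_all)) {
    stop("constant covariate: KS test undefined", call. = FALSE)
  }
  v_pts <- cv[pp$points]
  support <- sort(unique(v_all))
  f_win <- findInterval(support, sort(v_all)) / length(v_all)
  f_pts <- findInterval(support, sort(v_pts)) / length(v_pts)
  D <- max(abs(f_pts - f_win))
  frac <- pp$n / length(v_all)
  p <- if (D == 0 || frac >= 1) 1
       else kolmogorov_sf(sqrt(pp$n / (1 - frac)) * D)
  structure(list(statistic = D, z = NA_real_, p = p,
                 method = "ks_covariate", n = pp$n),
            class = "csr_test")
}

#' Complete-spatial-randomness filter
#'
#' Keeps the peaks whose Otsu-binarized signal pattern rejects the CSR
#' null. Each ion image is binarized, turned into a point pattern and
#' tested (Clark-Evans, or KS against a covariate image such as the TIC);
#' p-values are corrected across the current peak set and peaks with
#' adjusted `p < alpha` are kept. Peaks with a degenerate image or fewer
#' than 2 signal pixels cannot be tested: they are dropped with adjusted
#' p-value 1 recorded, and still count toward the Bonferroni denominator
#' (conservative).
#'
#' When no covariate is supplied the KS method uses the leave-one-out TIC:
#' for each tested peak, the per-pixel sum of all *other* peaks. The
#' peak's own intensities raise the TIC exactly at its own signal pixels,
#' so a plain TIC covariate makes even pure shot noise look non-random
#' whenever the peak set is small; excluding the tested peak removes that
#' circularity (with many hundreds of peaks the two covariates are
#' practically identical). Pass `covariate = tic_image(ds)` explicitly to
#' force the plain TIC.
#'
#' @param ds an `msi_dataset`.
#' @param method `"ks_covariate"` or `"clark_evans"`.
#' @param covariate covariate image for the KS method; `NULL` (default)
#'   uses the leave-one-out TIC described above.
#' @param adjust `"bonferroni"` (default), `"bh"` or `"none"`.
#' @param alpha significance level (default 0.001).
#' @param ... passed to the underlying test (e.g. `correction`).
#' @return A `filter_result`; scores are adjusted p-values and
#'   `extra$statistic`, `extra$p_raw`, `extra$n_points` record the tests.
#' @export
csr_select <- function(ds, method = c("ks_covariate", "clark_evans"),
                       covariate = NULL, adjust = c("bonferroni", "bh",
                                                    "none"),
                       alpha = 0.001, ...) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  loo_tic <- method == "ks_covariate" && is.null(covariate)
  tic_vec <- if (loo_tic) rowSums(ds$intensities)
  n <- n_peaks(ds)
  p_raw <- rep(NA_real_, n)
  stat <- rep(NA_real_, n)
  n_pts <- integer(n)
  for (k in seq_len(n)) {
    v <- image_values(ion_image(ds, k))
    mask <- tryCatch(v > otsu_threshold(v), error = function(e) NULL)
    if (is.null(mask) || sum(mask) < 2L) next
    pp <- point_pattern(mask)
    res <- tryCatch({
      if (method == "clark_evans") {
        clark_evans(pp, ...)
      } else {
        cov_k <- if (loo_tic) {
          matrix(tic_vec - ds$intensities[, k], ds$shape[1], ds$shape[2],
                 byrow = TRUE)
        } else covariate
        ks_covariate(pp, cov_k)
      }
    }, error = function(e) NULL) # e.g. constant covariate: untestable
    if (is.null(res)) next
    p_raw[k] <- res$p
    stat[k] <- res$statistic
    n_pts[k] <- pp$n
  }
  testable <- !is.na(p_raw)
  p_for_adjust <- ifelse(testable, p_raw, 1)
  p_adj <- switch(adjust,
    bonferroni = pmin(1, p_for_adjust * n),
    bh = stats::p.adjust(p_for_adjust, method = "BH"),
    none = p_for_adjust
  )
  p_adj[!testable] <- 1
  keep <- p_adj < alpha
  filter_result("csr", p_adj, keep,
                params = c(list(method = method, adjust = adjust,
                                alpha = alpha,
                                covariate = if (loo_tic) "loo_tic"
                                            else "supplied"), list(...)),
                ds,
                extra = list(statistic = stat, p_raw = p_raw,
                             n_points = n_pts))
}
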