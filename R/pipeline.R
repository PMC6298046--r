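#' Pipeline configuration
#'
#' Describes an end-to-end filtering run: the input dataset, an ordered
#' list of filter stages with their parameters, the ROI/reference method
#' and output locations. A split-merge stage, when present, must come
#' first: every downstream filter assumes one column per ion source.
#'
#' Stage entries are named lists with a `name` in `"split_merge"`,
#' `"reference"`, `"count"`, `"csr"` plus that filter's parameters.
#'
#' @param stages list of stage entries (see Details); may be empty.
#' @param input optional input path (imzML or matrix file).
#' @param roi_method `"kmeans"` or `"otsu"` (used by stages that need an
#'   ROI and by the reference filter default).
#' @param output_dir optional report/output directory.
#' @param seed integer seed recorded in the report and used for any
#'   stochastic step (k-means restarts).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = maldi_default_stages(), input = NULL,
                            roi_method = c("kmeans", "otsu"),
                            output_dir = NULL, seed = 0L) {
  roi_method <- match.arg(roi_method)
  known <- c("split_merge", "reference", "count", "csr")
  nm <- vapply(stages, function(s) s$name %||% "", character(1))
  if (any(!nm %in% known)) {
    stop("unknown stage name(s): ", paste(setdiff(nm, known),
                                          collapse = ", "), call. = FALSE)
  }
  if ("split_merge" %in% nm && which(nm == "split_merge")[1] != 1L) {
    stop("the split_merge stage must come first", call. = FALSE)
  }
  structure(list(stages = stages, input = input, roi_method = roi_method,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default MALDI filtering profile
#'
#' The stage list of the `maldi_default` profile: reference-similarity
#' filter (Spearman, threshold 0, binary ROI from 2-means clustering),
#' then the pixel-count filter (minimum 4 connected in-ROI pixels), then
#' the CSR filter (KS test against the TIC covariate, Bonferroni-adjusted
#' p-values at alpha 0.001).
#'
#' @return list of stage entries for [pipeline_config()].
#' @export
maldi_default_stages <- function() {
  list(
    list(name = "reference", measure = "spearman", threshold = 0,
         reference = "roi"),
    list(name = "count", min_pixels = 4L, aggressive = 0L),
    list(name = "csr", method = "ks_covariate", covariate = "tic",
         adjust = "bonferroni", alpha = 0.001)
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(stages = y$stages %||% maldi_default_stages(),
                  input = y$input,
                  roi_method = y$roi_method %||% "kmeans",
                  output_dir = y$output_dir,
                  seed = y$seed %||% 0L)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(list(stages = cfg$stages, input = cfg$input,
                        roi_method = cfg$roi_method,
                        output_dir = cfg$output_dir, seed = cfg$seed),
                   path)
  invisible(path)
}

#' Run a filtering pipeline
#'
#' Applies the configured stages in order; each stage sees only the peaks
#' that survived the previous stages. The ROI and reference images are
#' computed once on the input dataset (after any split-merge) and reused
#' by all stages, mirroring an analyst's workflow where the tissue mask
#' is fixed up front. Returns the filtered dataset plus a full report:
#' per-stage peak counts, per-peak score tables and every parameter used.
#'
#' @param cfg a `pipeline_config`, or a stage list.
#' @param ds an `msi_dataset`; when missing, loaded from `cfg$input`.
#' @return list of class `pipeline_run` with `dataset` (filtered),
#'   `report` (list: `stages`, per-stage `filter_result`s, counts) and
#'   `config`.
#' @export
run_pipeline <- function(cfg, ds = NULL) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  if (is.null(ds)) {
    if (is.null(cfg$input)) stop("no dataset and no input path",
                                 call. = FALSE)
    ds <- load_dataset(cfg$input)
  }
  t0 <- proc.time()[3]
  stage_results <- list()
  counts <- c(input = n_peaks(ds))
  roi <- NULL
  tic <- NULL
  need_roi <- function() {
    if (is.null(roi)) {
      roi <<- detect_roi(ds, method = cfg$roi_method, seed = cfg$seed)
    }
    roi
  }
  need_tic <- function() {
    if (is.null(tic)) tic <<- tic_image(ds)
    tic
  }
  for (st in cfg$stages) {
    if (n_peaks(ds) == 0L) {
      warning("no peaks left; stopping before stage '", st$name, "'",
              call. = FALSE)
      break
    }
    t_stage <- proc.time()[3]
    if (st$name == "split_merge") {
      sm <- merge_split_peaks(ds,
        tol_ppm = st$tol_ppm %||% 10,
        measure = st$measure %||% "spatial_chaos",
        overlap_max = st$overlap_max %||% 0.5,
        regularity_min = st$regularity_min %||% 0.5)
      ds <- sm$dataset
      stage_results[["split_merge"]] <- sm
      counts <- c(counts, split_merge = n_peaks(ds))
      # the reference/ROI must reflect the merged dataset
      roi <- NULL; tic <- NULL
      next
    }
    res <- switch(st$name,
      reference = {
        ref <- if (identical(st$reference %||% "roi", "roi")) need_roi()
               else make_reference(ds, st$reference)
        reference_filter(ds, ref, measure = st$measure %||% "spearman",
                         threshold = st$threshold %||% 0)
      },
      count = count_filter(ds, need_roi(),
                           min_pixels = st$min_pixels %||% 4L,
                           aggressive = st$aggressive %||% 0L),
      csr = {
        # "tic" means the leave-one-out TIC handled inside csr_select
        cov <- if (identical(st$covariate %||% "tic", "tic")) NULL
               else make_reference(ds, st$covariate)
        csr_select(ds, method = st$method %||% "ks_covariate",
                   covariate = cov, adjust = st$adjust %||% "bonferroni",
                   alpha = st$alpha %||% 0.001)
      }
    )
    res$elapsed <- proc.time()[3] - t_stage
    stage_results[[st$name]] <- res
    ds <- subset_peaks(ds, res$keep)
    counts <- c(counts, stats::setNames(n_peaks(ds), st$name))
  }
  structure(list(dataset = ds,
                 report = list(counts = counts, stages = stage_results,
                               seed = cfg$seed,
                               elapsed = proc.time()[3] - t0),
                 config = cfg),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:\n")
  cn <- x$report$counts
  for (i in seq_along(cn)) {
    cat(sprintf("  %-12s %d peaks\n", names(cn)[i], cn[i]))
  }
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' Emits a `summary.tsv` (per-stage surviving peak counts), one
#' `stage_<name>.tsv` per filter stage with the per-peak scores and keep
#' decisions, the filtered dataset as a matrix file, and optionally a PNG
#' gallery of the five dropped and five kept peaks with the largest mean
#' intensities.
#'
#' @param run a `pipeline_run`.
#' @param dir output directory (created if needed).
#' @param gallery also write `gallery.png` (default FALSE).
#' @param input_ds the pre-filter dataset; required for the gallery.
#' @return `dir`, invisibly.
#' @export
render_report <- function(run, dir, gallery = FALSE, input_ds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cn <- run$report$counts
  summary_df <- data.frame(stage = names(cn), peaks = as.integer(cn),
                           dropped = c(0L, -diff(as.integer(cn))))
  utils::write.table(summary_df, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(run$report$stages)) {
    st <- run$report$stages[[nm]]
    if (inherits(st, "filter_result")) {
      utils::write.table(as.data.frame(st),
                         file.path(dir, paste0("stage_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    } else if (!is.null(st$report) && nrow(st$report)) {
      utils::write.table(st$report,
                         file.path(dir, paste0("stage_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  write_peak_matrix(run$dataset, file.path(dir, "filtered_matrix.tsv"))
  if (gallery && !is.null(input_ds)) {
    write_gallery(run, input_ds, file.path(dir, "gallery.png"))
  }
  invisible(dir)
}

# 2-row ion-image gallery: top dropped peaks above, top kept peaks below.
write_gallery <- function(run, input_ds, path, n_each = 5L) {
  kept_ids <- run$dataset$peak_ids
  all_ids <- input_ds$peak_ids
  mean_int <- colMeans(input_ds$intensities)
  pick <- function(ids) {
    ids <- ids[order(mean_int[match(ids, all_ids)], decreasing = TRUE)]
    utils::head(ids, n_each)
  }
  top_dropped <- pick(setdiff(all_ids, kept_ids))
  top_kept <- pick(intersect(all_ids, kept_ids))
  grDevices::png(path, width = 160 * n_each,
                 height = 160 * 2)
  op <- graphics::par(mfrow = c(2, n_each), mar = c(0.5, 0.5, 2, 0.5))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  show <- function(id, tag) {
    img <- ion_image(input_ds, id)
    graphics::image(t(img$values)[, nrow(img$values):1],
                    col = grDevices::gray.colors(64, 0, 1), axes = FALSE,
                    main = sprintf("%s %s", tag, id), cex.main = 0.9)
  }
  for (id in top_dropped) show(id, "dropped")
  if (length(top_dropped) < n_each) {
    for (i in seq_len(n_each - length(top_dropped))) graphics::plot.new()
  }
  for (id in top_kept) show(id, "kept")
  invisible(path)
}
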