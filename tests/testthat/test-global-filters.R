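roi_and_dataset <- function(seed = 13) {
  # ROI = left 6 columns of a 12x12 grid
  roi <- roi_mask(col(matrix(0, 12, 12)) <= 6, origin = "external")
  inside <- blob_image(12, 12, 4:8, 2:5, value = 8)       # 20 px in ROI
  outside <- blob_image(12, 12, 4:8, 8:11, value = 8)     # 20 px outside
  set.seed(seed)
  list(roi = roi, inside = inside, outside = outside)
}

test_that("reference filter keeps in-ROI peaks and drops the rest", {
  f <- roi_and_dataset()
  ds <- dataset_from_images(f$inside, f$outside, matrix(0, 12, 12),
                            f$roi$mask * 3)
  res <- reference_filter(ds, f$roi, measure = "spearman", threshold = 0)
  # peak identical in support to the reference mask scores 1-ish and is kept
  expect_true(res$keep[4])
  # signal only in the ROI complement: anti-correlated, dropped
  expect_lt(res$scores[2], 0)
  expect_false(res$keep[2])
  # in-ROI blob: positively correlated, kept at threshold 0
  expect_gt(res$scores[1], 0)
  expect_true(res$keep[1])
  # all-zero column: -Inf sentinel, dropped
  expect_identical(res$scores[3], -Inf)
  expect_false(res$keep[3])
})

test_that("a peak image equal to the reference scores exactly 1", {
  img <- blob_image(8, 8, 2:5, 3:6, value = 2)
  ds <- dataset_from_images(img)
  res <- reference_filter(ds, msi_image(img), measure = "spearman")
  expect_equal(res$scores[1], 1)
})

test_that("reference filter keep-set is monotone in the threshold", {
  g <- generate_synthetic(shape = c(32, 32), n_structured = 6,
                          n_off_tissue = 4, n_noise = 4, seed = 17)
  roi <- g$truth$roi_true
  kept_prev <- NULL
  for (thr in c(-0.5, 0, 0.3, 0.8)) {
    res <- reference_filter(g$dataset, roi, threshold = thr)
    if (!is.null(kept_prev)) expect_true(all(kept_prev | !res$keep))
    kept_prev <- res$keep
  }
})

test_that("count filter level semantics follow the nesting", {
  f <- roi_and_dataset()
  in5 <- blob_image(12, 12, 4:8, 3, value = 7)             # 5 px inside
  iso <- matrix(0, 12, 12)
  iso[cbind(c(2, 6, 10), c(2, 4, 6))] <- 5                 # isolated singles
  both <- blob_image(12, 12, 2:3, 2:3, value = 6) +        # 4 px inside
          blob_image(12, 12, 6:10, 8:11, value = 6)        # 20 px outside
  ds <- dataset_from_images(in5, iso, both)
  r0 <- count_filter(ds, f$roi, min_pixels = 4, aggressive = 0)
  expect_true(r0$keep[1]); expect_equal(r0$scores[1], 5)
  expect_false(r0$keep[2])
  expect_true(r0$keep[3])
  r1 <- count_filter(ds, f$roi, min_pixels = 4, aggressive = 1)
  expect_false(r1$keep[3]) # outside blob dominates at level 1
  r2 <- count_filter(ds, f$roi, min_pixels = 4, aggressive = 2)
  # nesting: level 2 subset of level 1 subset of level 0
  expect_true(all(!r1$keep | r0$keep))
  expect_true(all(!r2$keep | r1$keep))
})

test_that("count filter keep-set is monotone in min_pixels", {
  g <- generate_synthetic(shape = c(32, 32), n_structured = 6,
                          n_off_tissue = 4, n_noise = 6, seed = 19)
  roi <- g$truth$roi_true
  kept_prev <- NULL
  for (mp in c(1, 4, 16, 64)) {
    res <- count_filter(g$dataset, roi, min_pixels = mp)
    if (!is.null(kept_prev)) expect_true(all(kept_prev | !res$keep))
    kept_prev <- res$keep
  }
})

test_that("all-ones ROI reduces aggressiveness levels to level 0", {
  expect_equal(sum(all_ones_roi(c(2, 3))$mask), 6L)
  g <- generate_synthetic(shape = c(24, 24), n_structured = 4,
                          n_off_tissue = 3, n_noise = 3, seed = 23)
  roi <- all_ones_roi(g$dataset$shape)
  r0 <- count_filter(g$dataset, roi, min_pixels = 4, aggressive = 0)
  r2 <- count_filter(g$dataset, roi, min_pixels = 4, aggressive = 2)
  expect_identical(r0$keep, r2$keep)
  # an all-ones mask cannot be a correlation reference
  expect_error(reference_filter(g$dataset, roi), "constant")
})
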