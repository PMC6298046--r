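test_that("Clark-Evans index is ~2 on a square lattice and ~0 when clustered", {
  # 32x32 lattice of points spaced 2 px in a window matching its density
  lat <- matrix(FALSE, 64, 64)
  lat[seq(1, 64, 2), seq(1, 64, 2)] <- TRUE
  ce <- clark_evans(point_pattern(lat), correction = "none")
  expect_equal(ce$statistic, 2, tolerance = 0.05)
  expect_gt(ce$z, 0)
  # all points inside a 3x3 block of a 100x100 window: strong aggregation
  m <- matrix(FALSE, 100, 100)
  m[50:52, 50:52] <- TRUE
  ce2 <- clark_evans(point_pattern(m))
  expect_lt(ce2$statistic, 0.2)
  expect_lt(ce2$p, 0.001)
  expect_error(clark_evans(point_pattern(matrix(c(TRUE, rep(FALSE, 8)),
                                                3, 3))), "2 points")
})

test_that("Clark-Evans is unbiased under the CSR null", {
  set.seed(41)
  Rs <- replicate(60, {
    pts <- cbind(runif(200, 0, 100), runif(200, 0, 100))
    clark_evans(point_pattern(pts, c(100, 100)), correction = "none")$statistic
  })
  expect_gt(mean(Rs), 0.95)
  expect_lt(mean(Rs), 1.05)
})

test_that("KS covariate statistic matches the quantile construction", {
  set.seed(43)
  cv <- matrix(rnorm(64 * 64), 64, 64)
  cv <- cv + seq_len(64) / 10 # ensure spatial structure, all unique
  # points = exactly the top-20% covariate pixels -> D ~ 0.8
  m <- matrix(cv >= quantile(cv, 0.8), 64, 64)
  res <- ks_covariate(point_pattern(m), msi_image(cv))
  expect_equal(res$statistic, 0.8, tolerance = 0.01)
  expect_lt(res$p, 1e-10)
  # points = all pixels -> D = 0
  res0 <- ks_covariate(point_pattern(matrix(TRUE, 64, 64)), msi_image(cv))
  expect_equal(res0$statistic, 0)
  expect_error(ks_covariate(point_pattern(m), msi_image(matrix(1, 64, 64))),
               "constant covariate")
})

test_that("csr_select limit cases and Bonferroni identities hold", {
  g <- generate_synthetic(shape = c(32, 32), n_structured = 5,
                          n_off_tissue = 0, n_noise = 5, seed = 47)
  ds <- g$dataset
  # alpha near 1 with no adjustment keeps every testable peak with p < alpha
  res <- csr_select(ds, adjust = "none", alpha = 0.999)
  expect_identical(res$keep, res$scores < 0.999)
  # Bonferroni with m = 1 equals the unadjusted test (explicit covariate:
  # a single-peak dataset has no leave-one-out TIC)
  one <- subset_peaks(ds, 1L)
  cov <- msi_image(matrix(seq_len(32 * 32) / 100, 32, 32))
  b1 <- csr_select(one, covariate = cov, adjust = "bonferroni",
                   alpha = 0.05)
  n1 <- csr_select(one, covariate = cov, adjust = "none", alpha = 0.05)
  expect_equal(b1$scores, n1$scores)
  expect_gt(b1$extra$n_points[1], 0)
  expect_error(csr_select(ds, alpha = 0), "alpha")
})

test_that("csr_select keep-sets are monotone in alpha and BH >= Bonferroni", {
  g <- generate_synthetic(shape = c(32, 32), n_structured = 6,
                          n_off_tissue = 3, n_noise = 6, seed = 53)
  ds <- g$dataset
  kept_prev <- NULL
  for (a in c(0.9, 0.1, 0.001, 1e-6)) {
    res <- csr_select(ds, adjust = "bonferroni", alpha = a)
    if (!is.null(kept_prev)) expect_true(all(kept_prev | !res$keep))
    kept_prev <- res$keep
  }
  for (a in c(0.05, 0.001)) {
    bonf <- csr_select(ds, adjust = "bonferroni", alpha = a)
    bh <- csr_select(ds, adjust = "bh", alpha = a)
    expect_true(all(!bonf$keep | bh$keep)) # Bonferroni subset of BH
  }
})

test_that("csr_select separates planted blobs from shot noise", {
  kept_blob <- 0; total_blob <- 0
  kept_noise <- 0; total_noise <- 0
  for (s in 1:5) {
    g <- generate_synthetic(shape = c(48, 48), n_structured = 10,
                            n_off_tissue = 0, n_noise = 10, seed = 60 + s)
    res <- csr_select(g$dataset, method = "ks_covariate",
                      adjust = "bonferroni", alpha = 0.001)
    lab <- g$truth$labels
    kept_blob <- kept_blob + sum(res$keep[lab == "structured"])
    total_blob <- total_blob + sum(lab == "structured")
    kept_noise <- kept_noise + sum(res$keep[lab == "noise"])
    total_noise <- total_noise + sum(lab == "noise")
  }
  expect_equal(kept_blob, total_blob)          # every blob peak kept
  expect_lte(kept_noise / total_noise, 0.1)    # >= 90% of noise dropped
})
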