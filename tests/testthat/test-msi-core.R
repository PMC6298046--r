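test_that("dataset invariants are enforced", {
  m <- matrix(1, 6, 2)
  expect_s3_class(msi_dataset(m, c(500, 600), c(2, 3)), "msi_dataset")
  expect_error(msi_dataset(-m, c(500, 600), c(2, 3)), "non-negative")
  expect_error(msi_dataset(m, c(600, 500), c(2, 3)), "increasing")
  expect_error(msi_dataset(m, c(500, 600), c(2, 2)), "does not match")
  expect_error(msi_dataset(m, 500, c(2, 3)), "length")
})

test_that("ion_image reshapes row-major and inverts exactly", {
  ds <- msi_dataset(cbind(1:6), mz = 500, shape = c(2, 3))
  expect_equal(ion_image(ds, 1)$values,
               matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE))
  # inverse pair on every column of a random dataset
  ds2 <- random_dataset(n_pix = 24L, n_peaks = 5L, shape = c(4, 6))
  for (k in seq_len(n_peaks(ds2))) {
    expect_identical(flatten_image(ion_image(ds2, k)),
                     ds2$intensities[, k])
  }
  # all-zero column is fine
  ds3 <- dataset_from_images(matrix(0, 4, 4), matrix(1:16, 4, 4))
  expect_true(all(ion_image(ds3, 1)$values == 0))
  expect_error(ion_image(ds2, 99), "out of range")
})

test_that("reference images match per-pixel oracles", {
  ds <- random_dataset(n_pix = 20L, n_peaks = 6L, shape = c(5, 4))
  med <- make_reference(ds, "median")
  oracle <- apply(ds$intensities, 1L, function(r) sort(r)[c(3, 4)])
  expect_equal(flatten_image(med), colMeans(oracle)) # median of 6 = mean of order stats 3,4
  expect_identical(flatten_image(make_reference(ds, "sum")),
                   flatten_image(tic_image(ds)))
  expect_equal(flatten_image(tic_image(ds)), rowSums(ds$intensities))
  # two identical peaks: mean reference equals either image
  img <- matrix(runif(16), 4, 4)
  ds2 <- dataset_from_images(img, img)
  expect_equal(make_reference(ds2, "mean")$values, img)
  # single peak: sum reference is that peak's image
  ds1 <- dataset_from_images(img)
  expect_equal(make_reference(ds1, "sum")$values, img)
})

test_that("pca1 reference is sign-fixed against the TIC", {
  ds <- random_dataset(n_pix = 40L, n_peaks = 8L, shape = c(8, 5), seed = 3)
  sc <- flatten_image(make_reference(ds, "pca1"))
  expect_gte(cor(sc, rowSums(ds$intensities)), 0)
  const <- msi_dataset(matrix(1, 16, 3), c(500, 600, 700), c(4, 4))
  expect_error(make_reference(const, "pca1"), "constant")
})

test_that("Otsu separates a perfectly bimodal image and rejects constants", {
  v <- c(rep(0, 50), rep(10, 50))
  thr <- otsu_threshold(v)
  expect_true(all((v > thr) == (v == 10)))
  expect_error(otsu_threshold(rep(3, 10)), "constant")
})

test_that("ROI detection finds separable structure", {
  # left half 10x the right half in every peak: 2-means finds the left half
  left <- matrix(0, 8, 8); left[, 1:4] <- 10
  right <- matrix(0, 8, 8); right[, 5:8] <- 1
  set.seed(4)
  ds <- dataset_from_images(left + right + 0.01 * matrix(runif(64), 8, 8),
                            2 * left + right)
  roi <- detect_roi(ds, "kmeans")
  expect_identical(roi$mask, left > 0)
  # otsu route on a bimodal reference
  ref <- msi_image(blob_image(8, 8, 2:5, 2:5, value = 10))
  roi2 <- detect_roi(ds, "otsu", reference = ref)
  expect_identical(roi2$mask, ref$values > 0)
  # external pass-through keeps the mask unchanged
  ext <- roi_mask(left > 0, origin = "external")
  expect_identical(ext$mask, left > 0)
})

test_that("k-means ROI is invariant to pixel order permutation", {
  g <- generate_synthetic(shape = c(16, 16), n_structured = 5,
                          n_off_tissue = 3, n_noise = 0, seed = 9)
  ds <- g$dataset
  roi1 <- detect_roi(ds, "kmeans")
  set.seed(11)
  perm <- sample.int(n_pixels(ds))
  # permute pixels, cluster, then unpermute the flattened mask
  dsp <- ds
  dsp$intensities <- ds$intensities[perm, ]
  fitp <- local({
    set.seed(0)
    stats::kmeans(dsp$intensities, centers = 2L, nstart = 10L,
                  iter.max = 50L)
  })
  ticp <- rowSums(dsp$intensities)
  roi_cl <- which.max(tapply(ticp, fitp$cluster, mean))
  maskv <- fitp$cluster == as.integer(names(roi_cl))
  unperm <- integer(length(perm)); unperm[perm] <- seq_along(perm)
  expect_identical(maskv[unperm], flatten_image(roi1))
})

test_that("all-zero-pixel handling: missing imzML pixels are zero-filled", {
  # hand-built 4x3 imzML covering 11 of 12 cells; the package writer is
  # not used, so this also cross-checks the reader against the format
  tmp <- withr::local_tempdir()
  xml_path <- file.path(tmp, "toy.imzML")
  ibd_path <- file.path(tmp, "toy.ibd")
  mzs <- c(500.1, 600.2)
  con <- file(ibd_path, "wb")
  writeBin(as.raw(rep(0, 16)), con)
  writeBin(mzs, con, size = 8)
  coords <- expand.grid(x = 1:3, y = 1:4)[-5, ] # drop pixel (x=2, y=2)
  offs <- 16 + 16 + (seq_len(nrow(coords)) - 1) * 16
  for (i in seq_len(nrow(coords))) writeBin(c(i, i + 0.5), con, size = 8)
  close(con)
  spectra <- vapply(seq_len(nrow(coords)), function(i) paste0(
    sprintf('<spectrum index="%d" id="s%d" defaultArrayLength="2">', i - 1, i),
    '<scanList count="1"><scan>',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>', coords$x[i]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>', coords$y[i]),
    '</scan></scanList><binaryDataArrayList count="2">',
    '<binaryDataArray><cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="16"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="2"/>',
    '<binary/></binaryDataArray>',
    '<binaryDataArray><cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', offs[i]),
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="2"/>',
    '<binary/></binaryDataArray></binaryDataArrayList></spectrum>'),
    character(1))
  writeLines(paste0(
    '<?xml version="1.0"?><mzML><fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>',
    '</fileContent></fileDescription><run><spectrumList count="11">',
    paste(spectra, collapse = ""),
    '</spectrumList></run></mzML>'), xml_path)
  expect_warning(ds <- read_imzml(xml_path), "zero-filled")
  expect_equal(n_pixels(ds), 12L)
  expect_equal(ds$shape, c(4L, 3L))
  expect_equal(ds$mz, mzs)
  # pixel (row 2, col 2) is the zero-filled one; its row-major index is 5
  expect_true(all(ds$intensities[5, ] == 0))
  # spectrum 1 sits at (x=1, y=1) -> pixel 1
  expect_equal(ds$intensities[1, ], c(1, 1.5))
})

test_that("imzML and matrix files round-trip a dataset", {
  tmp <- withr::local_tempdir()
  g <- generate_synthetic(shape = c(16, 16), n_structured = 3,
                          n_off_tissue = 1, n_noise = 1, seed = 5)
  ds <- g$dataset
  p1 <- file.path(tmp, "rt.imzML")
  write_imzml(ds, p1)
  back <- read_imzml(p1)
  expect_equal(back$mz, ds$mz, tolerance = 1e-6)
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-6)
  expect_equal(back$shape, ds$shape)
  p2 <- file.path(tmp, "rt.tsv")
  write_peak_matrix(ds, p2)
  back2 <- load_dataset(p2)
  expect_equal(back2$mz, ds$mz)
  expect_equal(back2$intensities, ds$intensities, ignore_attr = TRUE)
  # matrix file with explicit shape argument
  expect_equal(load_dataset(p2, "matrix", shape = c(16, 16))$shape,
               c(16L, 16L))
})
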