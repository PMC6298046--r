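Package: msifilter
Title: Spatially Aware Filtering of Mass Spectrometry Imaging Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to remove mass spectrometry imaging (MSI) peaks whose ion
    images have noisy or implausible spatial distributions. Provides
    split-peak detection and merging at a configurable m/z tolerance,
    a reference-image similarity filter (Pearson, Spearman, SSIM,
    normalized mutual information), a connected-pixel-count filter with
    graded aggressiveness, and complete-spatial-randomness tests
    (Clark-Evans nearest-neighbour index and a Kolmogorov-Smirnov test
    against a covariate image) with multiple-testing correction. Includes
    a minimal imzML reader/writer, a synthetic MSI data generator with
    known ground truth, and a configurable filtering pipeline with
    tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    xml2,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
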