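---
title: "Spatially aware filtering of MSI peak matrices: methods and design"
author: "msifilter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially aware filtering of MSI peak matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msifilter)
```

## The problem

A mass spectrometry imaging (MSI) experiment rasterizes a sample — most
often a tissue section — into a grid of pixels and acquires one spectrum
per pixel. After spectral preprocessing and peak matching (which this
package deliberately does not do), the data is a pixel × peak intensity
matrix: every matched peak has an *ion image*, its intensity painted onto
the grid. Typically over a thousand peaks survive matching, and a large
fraction of them are uninformative:

* **off-tissue ions** — matrix or solvent clusters whose spatial
  distribution is unrelated, often complementary, to the tissue;
* **shot-like noise** — sparse, spatially random pixel spikes resembling a
  homogeneous Poisson process;
* **split peaks** — a single ion source that random peak shifts have
  smeared across two or more contiguous m/z bins during matching.

None of these can be recognized from the spectral dimension alone, but all
of them betray themselves spatially. `msifilter` implements four tools that
exploit this: split-peak merging, a reference-image similarity filter, a
connected-pixel-count filter, and complete-spatial-randomness (CSR) tests.
Filtering typically shrinks the peak set severalfold, which both
de-noises downstream multivariate analysis and makes it far more
interpretable.

## Data model

An `msi_dataset` holds the non-negative intensity matrix (rows = pixels,
columns = peaks), the strictly increasing m/z vector and the grid shape.
Pixels are stored in **row-major** order: pixel `p` sits at grid row
`(p - 1) %/% n_cols + 1`, column `(p - 1) %% n_cols + 1`, and imzML
1-based `x`/`y` positions map to column `x`, row `y`. One convention
everywhere prevents transposed ion images. Indices are 1-based, as is
natural in R. Grid cells with no acquired spectrum are zero-filled on
import (with a warning): the spatial filters need a complete rectangle.

Intensities are filtered raw, as delivered by peak matching. Per-pixel
TIC normalization is available (`normalize_tic()`) for instruments with
strong pixel-to-pixel sensitivity drift, but it is not a default: it
rescales every pixel's total to 1, which flattens the sum reference image
and can only hurt ROI detection, so if used it should follow ROI
detection or be combined with the k-means route.

## Otsu binarization and connected components

Most of the filters first split an ion image into "signal" and
"background" pixels with Otsu's threshold: the cut maximizing the
between-class variance $\omega_0\omega_1(\mu_0-\mu_1)^2$. Candidate cuts
are the interior edges of 256 equal-width bins spanning the image range,
classes are `value <= t` versus `value > t` on the raw pixel values, and
the first maximizing edge is returned, so the result is deterministic and
identical to an exhaustive search over the same grid (a property the test
suite asserts). "Signal" is *strictly greater* than the threshold, which
keeps an exactly-zero background out of the signal class. A constant
image has no threshold and is treated as degenerate; every filter drops
such peaks explicitly rather than erroring mid-run.

Connected components are labeled with 8-connectivity by default —
diagonally touching tissue structures stay one object — with a
4-connectivity flag throughout. The labeling is an iterative minimum-label
propagation, deterministic, and is verified against a flood-fill oracle in
the tests.

## Spatial regularity measures

Three scalar measures say how "structured" a single ion image is; all are
oriented so that **higher = more regular**, in $[0, 1]$:

* **Scattered-pixel ratio** — after Otsu binarization, the fraction of
  signal pixels outside the largest connected component, subtracted from
  one. "Disconnected signal pixels" is ambiguous in the abstract; defining
  it against the largest component makes the measure monotone and bounded,
  with 1 attained exactly by a single blob.
* **Spatial chaos** — the nonzero intensities are thresholded at 64
  quantile levels; at each level the fraction of signal pixels with no
  signal neighbor is computed, and chaos is the mean over levels
  (regularity is its complement). Binarization at a level uses
  `value >= threshold` so the top level keeps the maximal pixels — with a
  strict inequality a two-valued image would have no signal at any level.
  This is a deliberately simple variant: the published "measure of chaos"
  construction based on edge detection is not reproduced here, only its
  orientation (lower chaos = more structure). The measure is pluggable.
* **Gini index** — $G = \sum_{ij} |x_i - x_j| / (2 n^2 \bar x)$,
  computed via the sorted-vector identity and tested against the pairwise
  sum. 0 means perfectly even intensity; near 1 means the intensity mass
  sits on few pixels. It is scale-invariant and needs no binarization,
  but note its orientation differs in kind from the other two: it
  measures concentration, not connectedness, so shot noise also scores
  high. It is therefore not the default in the split-peak evaluator.

## Split-peak merging

Candidates are maximal runs of adjacent peaks whose consecutive m/z gaps
are within tolerance, `mz[i+1] - mz[i] <= tol * 1e-6 * mz[i+1]` — the
transitive closure, since a 3-way split is pairwise contiguous. The
tolerance is expressed in ppm (default 10, an absolute-Da option exists)
because instrumental mass error scales multiplicatively.

A candidate group is merged when three conditions hold on the
Otsu-binarized member images:

1. every pair of signal masks overlaps at most `overlap_max` (default
   0.5), with overlap $|A \cap B| / \min(|A|, |B|)$ — true split peaks
   partition one source, so their supports are essentially disjoint,
   whereas genuinely distinct isobars co-localize;
2. at least one member reaches regularity `regularity_min` (default 0.5)
   — some member must look like structured signal rather than noise;
3. the pixel-wise sum of the members is at least as regular as the best
   member — merging must repair structure, not degrade it.

The default regularity measure is **spatial chaos**. The reason is
geometric: a split member is a random pixel subset of a structured
region. At a 2-way split the member density (~0.5) is above the
8-neighborhood site-percolation threshold (~0.41), but a 3-way split
(~0.33) is below it, so the largest-component-based scatter ratio
collapses for 3-way splits while the isolated-pixel-based chaos measure
degrades only mildly (a pixel at density 1/3 still almost always has a
neighbor). On the synthetic generator, split members score 0.79–0.94
chaos-regularity against 0.10–0.23 for shot noise, so the 0.5 default
sits in a wide gap; the same margin argument would not hold for the
scatter ratio.

Merging sums the member columns pixel-wise — conserving total ion count
exactly, which `max` would not — and places the merged peak at the
intensity-weighted mean of the member m/z values (the m/z assignment rule
is not standardized anywhere; the weighted mean keeps the merged position
inside the group span and closest to the dominant member). Because a
merge changes adjacency, the procedure iterates to a fixed point (at most
3 passes). Split-merging should always run *before* the other filters,
which assume one column per ion source; `pipeline_config()` enforces
this ordering.

## Reference similarity filter

Each peak is scored by the similarity between its ion image and a
reference describing where signal is expected. The reference is either a
continuous image — per-pixel `sum`, `mean`, `median` or first principal
component scores of the whole matrix (PC sign fixed to correlate
non-negatively with the TIC, since a principal axis has arbitrary sign) —
or a binary ROI. The ROI comes from Otsu-thresholding a reference image,
from 2-means clustering of the pixel intensity vectors (fixed seed 0, 10
restarts; the ROI is the cluster with the larger mean TIC, a tie-break
k-means itself does not provide), or from an external pre-registered
raster (`read_raster()`, `roi_mask()`); registration itself is out of
scope.

Four similarity measures are available: Pearson and Spearman correlation
of the flattened pixel vectors; SSIM (mean local structural similarity,
Gaussian window $\sigma = 1.5$ on an 11×11 support, stabilizers
$C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$ with $L$ the pooled dynamic range,
reflect padding so the window weights always sum to one); and normalized
mutual information $I(A;B)/\sqrt{H(A)H(B)}$ on 256-bin equal-width
histograms (a binary mask keeps its two natural levels). The geometric
mean normalization keeps NMI symmetric and in $[0,1]$.

The keep rule is `score > threshold`, **strictly**, with default
threshold 0: ions localized in *small* sub-regions of the ROI are still
weakly positively correlated with it and survive, while the strict
inequality removes peaks scoring exactly 0. A constant ion image carries
no spatial information and cannot be scored; such peaks get a $-\infty$
sentinel and are dropped. An all-ones ROI is rejected as a correlation
reference (a constant vector has no correlation) — that degenerate ROI
exists for the count filter, not this one.

## Pixel-count filter

Shot noise fires isolated pixels; real ions fill contiguous regions at
least as large as the smallest meaningful anatomical sub-structure. Each
ion image is binarized at its own Otsu threshold (background level is a
per-peak notion), components are labeled, and the peak must have a
connected component whose ROI-restricted part has at least `min_pixels`
pixels (default 4). Component size is counted *inside* the ROI (a flag
switches to whole-component size): a component draped across the ROI
boundary should not be credited for its off-tissue part.

Aggressiveness levels tighten this by looking outside the ROI, and are
nested by construction (level 2 ⊆ level 1 ⊆ level 0):

* level 0 — the in-ROI cluster condition alone;
* level 1 — additionally, the largest ROI-intersecting component must be
  at least as large as the largest component lying fully outside the ROI;
* level 2 — additionally, more signal pixels inside the ROI than outside.

With an all-ones ROI (no off-tissue region acquired) there are no
outside pixels and all three levels coincide.

## Complete spatial randomness filter

The least aggressive filter asks only: could this peak's signal pixels be
a uniformly random scatter? The Otsu signal mask becomes a point pattern
(pixel centers, unit spacing) in the grid-rectangle window, and one of
two tests is applied per peak.

**Clark–Evans.** $R = \bar d_{obs} / \bar d_{exp}$, the mean
nearest-neighbor distance against its CSR expectation
$1/(2\sqrt{\lambda})$, $\lambda = n/A$. $R < 1$ means aggregation, and
the default alternative is one-sided toward aggregation, since
informative ions cluster. The normal deviate uses the Donnelly boundary
correction by default: in pixel-grid windows at realistic point counts
the border band is a substantial fraction of the window (for $n = 100$
in a 64×64 window, roughly a fifth), border points inflate
$\bar d_{obs}$, and the uncorrected one-sided test collapses to a type-I
error below 0.01 at nominal 0.05 — the test suite measures 0.04 with the
correction. `"none"` and `"toroidal"` remain available; the reported $R$
statistic is always the plain index.

**Kolmogorov–Smirnov against a covariate.** Under CSR the pattern
samples pixels uniformly, so the covariate values at the pattern points
are distributed like the covariate over the whole window:
$D = \sup_v |\hat F_{points}(v) - F_{window}(v)|$, with both CDFs
right-continuous on the covariate's discrete support (ties in image
values are handled naturally). Because the $n$ pattern pixels are a
subset of the $N$ window pixels, the CDF difference has variance
$(1 - n/N)\,F(1-F)/n$; the p-value therefore refers
$\sqrt{n/(1-n/N)}\,D$ to the Kolmogorov distribution. With the naive
$\sqrt{n}$ scaling the test is conservative at any appreciable sampling
fraction (long-run type-I error 0.026 at a 10% fraction, versus 0.046
with the finite-population effective size — both measured by the test
suite's null simulations).

**The covariate.** The canonical covariate is the TIC image. One subtlety
matters at small peak counts: the TIC contains the tested peak, and a
peak's own intensities raise the TIC exactly at its own signal pixels, so
against the plain TIC even pure shot noise rejects CSR decisively once
the peak set is small (with ~50 peaks, shot-noise peaks reach
$D \approx 0.2$–$0.4$). The default covariate is therefore the
**leave-one-out TIC** — the per-pixel sum of all *other* peaks. With
many hundreds of peaks the two covariates are practically identical; an
explicitly supplied covariate image is always used verbatim.

P-values are corrected across the tested peak set (Bonferroni by
default, with Benjamini–Hochberg and no correction as options) and peaks
with adjusted $p < \alpha$ (default 0.001) are kept. Peaks that cannot
be tested — degenerate images, fewer than 2 signal pixels, or a
degenerate covariate — are dropped with adjusted p-value 1 recorded, and
still count toward the Bonferroni denominator, which is conservative in
the right direction.

## The pipeline and its default profile

`run_pipeline()` applies stages in order, each seeing the survivors of
the previous one; the ROI, computed once (after any split-merge stage,
whose merging changes the matrix the ROI is computed from), is shared by
all stages. The `maldi_default` profile is: Spearman similarity against
the 2-means ROI at threshold 0, count filter at 4 connected in-ROI
pixels, then the KS CSR filter with the TIC covariate under Bonferroni at
$\alpha = 0.001$. Split-merge is not part of the default profile and can
be prepended. Reports record per-stage counts, per-peak scores and all
parameters; a run is deterministic given the configured seed (the only
stochastic component is k-means initialization).

```{r example}
g <- generate_synthetic(seed = 1)
run <- run_pipeline(pipeline_config(seed = 0), ds = g$dataset)
run
table(truth = g$truth$labels,
      kept = g$dataset$peak_ids %in% run$dataset$peak_ids)
```

## The synthetic generator

All development-time validation runs on generated data with known ground
truth (`generate_synthetic()`). It emulates the four signal classes the
filters target: structured peaks (smooth positive fields on a
smooth-thresholded random-blob ROI occupying 30–60% of the grid, plus
additive Gaussian noise at $\sigma = 0.05$ of the unit amplitude),
off-tissue peaks (the same construction on the ROI complement), shot
noise (each pixel fires independently with probability 0.05, uniform
marks in $[0.5, 1]$ — a Bernoulli pixel process, the grid analogue of a
homogeneous Poisson process, with marks deliberately as large as real
signal), and split groups (a structured image partitioned across 2–3
columns at m/z gaps of 1–4 ppm). Non-split peaks are at least 50 ppm
apart on an m/z axis drawn in [500, 900]. Everything is reproducible
bit-for-bit from the seed.

What it does **not** emulate: isotope envelopes, mass-dependent peak
widths, correlated (structured) background noise, intensity gradients
from matrix application, or registration error in external images. A
filter passing on this generator is therefore evidence that the spatial
logic is correct, not a guarantee on any particular instrument's data;
the default thresholds remain the user-facing tuning points on real
data.

Test and validation problem sizes — 64×64 grids, 50 peaks, 20 generator
seeds for the end-to-end contract, 200–600 null simulations for the CSR
calibration — were chosen as the smallest sizes at which the binomial
noise of the measured rates is comfortably below the contract margins.

## Known limitations

* The imzML reader/writer is minimal: continuous mode, plus processed
  mode only when all spectra share one m/z axis (peak matching belongs
  upstream). No ibd checksums are written or verified.
* The spatial-chaos measure is a variant construction (see above), not a
  reimplementation of the edge-detection-based original.
* CSR testing offers Clark–Evans and the covariate KS test only; no
  Cramér–von Mises/Anderson–Darling variants, no inhomogeneous Poisson
  modeling, and the exact small-n KS distribution is not implemented
  (the asymptotic reference is accurate at the point counts the Otsu
  masks produce).
* Multi-class ROIs and per-region thresholds are out of scope; the ROI
  is one binary mask.
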