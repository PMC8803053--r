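---
title: "Adipocyte morphometry with adipoquant: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adipocyte morphometry with adipoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

## The measurement problem

In haematoxylin–eosin (H&E) stained sections of adipose tissue, the lipid
content of each adipocyte dissolves during processing, so a fat cell appears
as a large, nearly white lumen bounded by a thin stained membrane. Fat cell
size (cross-sectional area, or the circular-equivalent diameter
$d = 2\sqrt{A/\pi}$) and cell density are standard readouts of adipose
tissue remodelling in obesity research. `adipoquant` implements a complete
measurement pipeline for this setting:

1. a **trainable pixel classifier** that separates unstained lumina from
   *any* stained tissue;
2. an **object builder** that converts the binary fat mask into discrete
   cells (hole filling, minimum size, watershed splitting of touching
   cells);
3. **morphometry** over a region of interest (ROI) after area-range
   filtering;
4. **inter-method agreement statistics** (intraclass correlation,
   Bland–Altman, paired regression) for validating one measurement method
   against another;
5. **tiled processing** so regions far beyond a single in-memory raster can
   be analysed; and
6. a **synthetic tissue generator** that provides calibrated images with
   exact per-cell ground truth, the backbone of the package's validation.

## Pixel classification

The classifier is a two-class random forest applied per pixel at a fixed
*working resolution* (default 1 µm/px; images are resampled before feature
extraction, so all physical thresholds stay in µm). A deliberate design
point, inherited from practical experience with stained sections: the two
classes are *fat lumen* versus *any stained tissue*. Distinguishing
membranes from other stained structures is not attempted — it is both
unnecessary for lumen measurement and fragile across staining variation.

Features per pixel (see `default_feature_config()`): the raw R, G, B
channels plus, per channel, Gaussian-smoothed intensity (σ = 2 and 4 px),
gradient magnitude of the smoothed channel (σ = 2), and a
Laplacian-of-Gaussian (σ = 2) — 15 features. The forest has 51 trees
(odd, so majority votes cannot tie), √F features per split, unlimited
depth, and a fixed training seed; a pixel is called fat when the forest's
fat probability is at least 0.5, which for hard-voting trees is exactly the
majority vote. Larger scale sets (σ up to 8, more filters) can be requested
through `default_feature_config()`'s arguments; on the synthetic palette the
compact set already reaches held-out accuracy ≈ 1.0, and it keeps
whole-slide classification tractable on one CPU.

Training annotations are sparse label masks (0 = unlabelled, 1 = fat,
2 = tissue). Training fails loudly if a class is absent. A held-out
fraction (default 20%) of the labelled pixels is set aside before fitting
and reported as `holdout_accuracy`. `add_training_annotations()` folds new
labels into the stored training pool and refits with the same seed — the
annotate-misclassified-regions improvement loop.

Implementation note: the forest is grown by `ranger`, but pixel-scale
prediction uses the package's own compiled tree-walker over the stored
forest (verified bit-identical to `ranger`'s predictions in the test
suite). Likewise the feature filters are direct separable convolutions with
replicated borders; a delta-image test pins them to a brute-force
convolution oracle.

## From mask to cells

`mask_to_objects()` applies, in order:

* **fill_small_holes** — background regions 8-connected, fully enclosed by
  fat, with area *strictly below* `min_hole_size_um2` (default 30 µm²) are
  filled; border-touching background is never a hole.
* **remove_small_objects** — 4-connected fat components with area below
  `min_object_size_um2` (default 20 µm²) are discarded; a component exactly
  at the threshold is kept.
* **split_touching** — per component, watershed on the Euclidean distance
  transform; distance maxima shallower than `watershed_h` (default 2 px)
  are merged before seeding, so convex single cells pass through unchanged.
  Splitting reassigns pixels, never deletes them.

The defaults (min object 20 µm², min hole 30 µm², splitting on) are the
validated create-objects settings of the protocol this package implements.
Connectivity duality (fat 4-connected, background 8-connected) prevents fat
from leaking diagonally through one-pixel membrane gaps — the main cause of
falsely conjoined cells. Thresholds are converted to pixels as
`threshold / pixel_size²` and compared as real numbers, so behaviour is
resolution-independent. All inclusive/strict boundary conventions above are
fixed by tests at the exact threshold.

Each object carries its pixel count, area (`pixels × pixel_size²`),
circular-equivalent diameter, centroid and a traced boundary polygon in
micrometre slide coordinates (outer contour along pixel edges, collinear
vertices merged), exportable as GeoJSON for overlay in slide viewers.

## Morphometry

`summarize_morphometry()` reports, for the objects surviving an inclusive
area filter (default 500–100,000 µm², the working range for human
adipocytes): count, mean ± SD area, mean ± SD of the *per-cell* diameters
(the mean of diameters, not the diameter of the mean — for right-skewed
size distributions the former is strictly smaller), and density per
10⁶ µm². SDs are sample (n−1) SDs. The density denominator is the
user-drawn ROI polygon area; a convex hull of the detected centroids is
available via `density_denominator = "hull"` for workflows where no ROI is
drawn. With zero surviving objects the means are `NA` and the density 0;
with one object the SDs are `NA`.

## Agreement statistics

`icc_consistency()` implements the single-measure intraclass correlation
under a two-way mixed-effects model aimed at consistency,
$ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)$, with the F test
$MS_R/MS_E$ on $(n-1)$ and $(n-1)(k-1)$ degrees of freedom and the
Shrout–Fleiss confidence interval. The consistency form is invariant to a
fixed offset between methods — appropriate when one method reads
systematically slightly smaller cells, as unsupervised lumen detection
does against a manually corrected reference. The absolute-agreement form
ICC(A,1) (McGraw–Wong interval) is available via `type = "agreement"`.
When all values are identical both mean squares vanish and the result is
flagged `degenerate` rather than reported as 1. Reliability wording
follows the lower CI bound: ≥ 0.90 excellent, ≥ 0.75 good, ≥ 0.50
moderate, else poor.

`bland_altman()` uses differences A − B, their mean and sample SD, and
limits of agreement at mean ± 1.96 SD, plus the per-subject (mean,
difference) table for plotting. `paired_regression()` is ordinary least
squares of B on A with Pearson r. Rows with a missing value in either
method are dropped listwise and counted.

## Tiled analysis of large regions

Single-raster analysis of very large regions is the classic failure mode of
desktop slide tools, so `tiled_analysis()` processes the ROI in square
core tiles (default 2000 µm — the validated 2–4 ×10⁶ µm² working unit)
expanded by a halo (default 150 µm, about twice a generous mean adipocyte
diameter). Cores partition the ROI half-open, so every pixel centre has
exactly one owner. Objects strictly inside a core are kept directly.
Objects crossing a core boundary contribute their pixel sets, in global
working-grid coordinates, to a merge pool; the pooled pixels are unioned
across neighbouring tiles (exact de-duplication, order-independent),
re-processed with the same hole/size/split rules, and measured once. A
merged object that still touches a tile's outer edge means the halo was too
small; the run warns and counts such objects.

Because classification is per-pixel with finite feature support (≤ 3σ + 1
px), a halo much wider than the largest feature radius makes the tiled and
untiled runs agree *exactly* for every object — a property the test suite
asserts per object. With a tile-map source (`write_tile_map()`:
`index.json` plus one calibrated PNG per tile), only the tiles a request
overlaps are ever decoded, bounding memory by tile size rather than ROI
size. Plain PNG/TIFF sources are supported but must be decoded whole per
read; tile maps are the intended route for whole-slide work.

## The synthetic tissue generator

`generate_tissue()` builds ground truth first and renders second:

1. Seed points with a minimum-spacing rejection rule (dart throwing) at an
   intensity calibrated so that the number of *whole* cells — cells not cut
   by the region border — matches `target_density`. Seeds are placed on a
   border-padded region and the intensity inflated by
   $WH/((W-d)(H-d))$, $d$ the nominal cell diameter.
2. Voronoi tessellation of the seeds (`deldir`); each convex tile is offset
   inward by half the membrane thickness (default 3 µm), so neighbouring
   lumina are separated by a stained membrane of the requested thickness.
3. Lognormal multiplicative size jitter, *shrink-only* (factors capped at
   1 so polygons can never overlap), topping the tessellation's own area
   spread up toward `cell_size_cv` (default 0.45, consistent with reported
   SD/mean ratios for human adipocytes). The cap truncates the upper tail,
   so the realized CV undershoots the requested value (≈ 0.35 at paper
   scale) — a known limitation, chosen over overlap-prone expansion.
4. Border-cut cells are dropped from the ground truth *and* not rendered;
   the border area renders as stained tissue. Detection and truth therefore
   see the same cell population, mirroring protocols that annotate whole
   adipocytes only.
5. Rendering at `pixel_size_um` (default 1 µm/px): membrane colour
   RGB(168, 112, 160), lumen RGB(245, 243, 246), Gaussian noise (SD 4 of
   255). Cell polygons and areas are defined geometrically in µm,
   independent of the raster — re-measuring the polygons reproduces
   `cell_areas_um2` exactly, and halving the pixel size changes only the
   raster.

Quality grades emulate the visual good/average/poor grading of section and
staining quality. `apply_spillover()` tints, per cell, the band of the
lumen adjacent to the membrane covering `spillover_fraction` of the lumen
area (convex scaling about the centroid: core scale $\sqrt{1-f}$) toward a
desaturated membrane colour with per-cell random strength — the
"spilling of staining" artifact that makes poor sections under-segment.
`average` applies half the fraction, `poor` the full fraction (default
0.4). The grade labels are generator inputs, not computed image-quality
scores.

What the generator deliberately does **not** emulate: nuclei, vessels,
crown-like structures, stain deconvolution-level colour variation,
out-of-focus blur, or 3-D sectioning effects. Passing the recovery tests
therefore demonstrates the pipeline's geometric and statistical
correctness, not robustness to every real-world staining pathology — the
spillover mode probes exactly one such pathology, the one that dominates
poor-quality sections in practice.

## Validation strategy and problem sizes

The reference data behind the original inter-method comparison are not
public, so validation is property- and recovery-based, all computed at run
time:

* closed-form identities (circular diameter, scale equivariance,
  density–count recovery);
* brute-force oracles: flood-fill labeling/hole-filling/size-removal on
  random 64×64 masks, direct-convolution features, two-way-ANOVA ICC via
  `stats::aov`, normal-equation regression;
* ground-truth recovery on twenty seeded 2×10⁶ µm² good-quality regions at
  density 150 (≈ 300 cells each, the scale of a typical measurement
  field): per-region cell count and mean area within ±5% of truth, and
  ICC ≥ 0.95 between measured and true per-region mean areas;
* directional artifact behaviour: spillover at fraction ≥ 0.4 strictly
  decreases the detected mean area on identical geometry;
* tiled equivalence: a ~7×10⁶ µm² region analysed whole versus in 4 tiles
  (exact count agreement, total area within 0.5%), and a ~60×10⁶ µm²,
  ≈ 12,000-cell synthetic slide processed tile-wise from a tile map with
  count within ±5% of truth;
* determinism: seeded generation and seeded CLI runs are byte-identical
  across invocations, verified through output checksums recorded in each
  run's manifest.

These sizes were chosen to mirror the measurement units the protocol was
validated on (2×10⁶ µm² fields, multi-million-µm² regions, a whole-slide
scale run) while remaining comfortable on a single CPU.
`scripts/acceptance.R` re-runs these studies (with eight recovery regions,
and without the whole-slide run, which lives in the test suite) and
reports the measured quantities as JSON; see the README.

## Numerical conventions

* Pixel (r, c) covers the half-open µm square with centre
  `origin + (c−0.5, r−0.5)·pixel_size`; rasterization and region reads use
  pixel-centre membership, so adjacent boxes partition an image exactly.
* µm²→px² thresholds are real-valued (no rounding).
* Ties at forest probability 0.5 are impossible with an odd tree count and
  hard-voting leaves; the 0.5 threshold maps to majority vote.
* All randomness (seed points, jitter, noise, pixel subsampling, forest
  growth) is derived from explicit integer seeds; repeated calls are
  bit-identical. Rendering noise is seeded per window from the spec seed
  and window origin, so windowed renders are individually deterministic.
* Degenerate inputs fail explicitly: zero-cell tessellations, single-class
  annotations, uncalibrated images, non-positive ROI areas, zero-variance
  regression predictors, all-identical ICC matrices.
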