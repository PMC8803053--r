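# adipoquant

Adipocyte (fat cell) morphometry from H&E-stained histology, in R.

In haematoxylin–eosin sections of adipose tissue the lipid dissolves during
processing, leaving each adipocyte as a large near-white lumen bounded by a
thin stained membrane. Cell cross-sectional area, circular-equivalent
diameter and density are standard readouts of adipose remodelling in
obesity research, and measuring them over thousands of cells by hand is
impractical. `adipoquant` implements the full measurement pipeline:

* a **trainable random-forest pixel classifier** separating unstained fat
  lumina from *any* stained tissue, applied at a fixed working resolution
  (µm-calibrated throughout);
* **object creation** from the binary fat mask — hole filling (min hole
  30 µm²), minimum object size (20 µm²), and watershed splitting of
  touching cells;
* **morphometry** per region of interest after inclusive area-range
  filtering (default 500–100,000 µm²): count, mean ± SD area,
  circular-equivalent diameter d = 2·√(A/π) (per-cell mean), and density
  per 10⁶ µm²;
* **inter-method agreement statistics**: single-measure intraclass
  correlation under a two-way mixed-effects model aimed at consistency,
  ICC(C,1) = (MS_R − MS_E)/(MS_R + (k−1)·MS_E), with Shrout–Fleiss 95% CI
  and F test; Bland–Altman mean difference and limits of agreement; paired
  OLS regression;
* **tiled analysis** of large regions (default 2000 µm cores + 150 µm
  halos) with exact re-assembly of cells crossing tile boundaries, so
  multi-million-µm² regions and whole-slide-scale images are processed
  without ever holding a full-region raster;
* a **synthetic adipose-tissue generator** (Voronoi cells, thin stained
  membranes, lognormal size jitter, optional staining-spillover artifacts)
  with exact per-cell ground truth, used to validate every stage.

See the methods vignette (`vignettes/adipoquant-methods.Rmd`) for the
models, parameter defaults and validation design.

## Worked example

Generate a calibrated synthetic region at the standard measurement scale
(2×10⁶ µm², target density 150 cells/10⁶ µm²), train the classifier on
sparse annotations, and measure:

```r
library(adipoquant)

spec <- tissue_spec(region_width_um = 2000, region_height_um = 1000,
                    target_density = 150, seed = 100)
gen <- generate_tissue(spec)
gen$truth
#> <ground_truth> 293 cells in 2000 x 1000 um; mean area 4778 um^2 (CV 0.39)

labels <- training_labels_from_truth(gen, n_per_class = 2000, seed = 1)
model <- train_pixel_classifier(list(list(image = gen$image, labels = labels)),
                                seed = 7)
model
#> <pixel_classifier_model> 15 features, 51 trees, 1 um/px working, held-out accuracy 1.000

res <- analyze_image(gen$image, model)
res$summary
#> <morphometry_summary> n = 293 | mean area 4777.7 +/- 1866.7 um^2 | mean diameter 76.6 +/- 14.7 um | density 146.5 /1e6 um^2
```

The detected count (293) equals the ground-truth count, and the measured
mean area (4777.7 µm²) matches the true polygon mean (4777.6 µm²) to
0.01% — the lumen raster reproduces the generating geometry. Objects
export as GeoJSON (µm slide coordinates, loadable as annotations in common
slide viewers) or flat CSV via `objects_to_geojson()` / `objects_to_csv()`.

Comparing two measurement methods over a sample series:

```r
pm <- read_paired_csv("paired.csv")   # subject_id, a_value, b_value
agreement_analysis(pm)
#> <agreement_result> variable 'value', n = 20 (0 dropped)
#> <icc_result> ICC(C,1) = 0.984 [0.961, 0.994], F(19,19) = 125.61, p = 4.74e-16 (excellent)
#> <bland_altman> mean diff 16.16 (SD 158.6), LoA [-294.6, 327], n = 20
#>   regression: B = -513.6 + 1.095 A, r = 0.9893
```

A command-line interface wraps the same functions
(`inst/cli/adipoquant`): `simulate`, `train`, `analyze` (with `--tiled`,
`--min-object`, `--min-hole`, `--area-range 500:100000`), and `compare`.
Every run writes a `manifest.json` with arguments, seed, versions and
output checksums; seeded runs are byte-reproducible.

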