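# simscorr — correlative EM / NanoSIMS image analysis

`simscorr` automates the correlation of transmission electron microscopy
(EM) images with NanoSIMS ion-count images for per-organelle isotopic
quantification. It is written for SIMS/EM labs doing pulse–chase isotope
labeling who need to segment organelle instances on large EM images,
transfer the masks onto the SIMS raster, and turn corrected ion-count
ratios into turnover kinetics — without hand-drawing hundreds of ROIs.

## What it computes

**Segmentation on mega-images.** Fixed-frame backends (default 640 px) see
tiles, not mega-images, so each image is reflect-padded and cut into
disjoint tiles `n_passes` times with grid origins offset by
`frame / n_passes` px; instances truncated at one pass's tile boundary are
interior at another. Per-tile detections are compiled by IoU-linking
(transitive closure at IoU ≥ 0.5), support thresholding (≥ 2 of 5 passes
by default), mask union, and per-class morphological filtering (minimum
area; minimum circularity `4πA/P²` for circular classes such as vesicles,
which removes boundary-truncated partial detections). A deterministic toy
backend ships for testing; a trained neural detector plugs in behind the
same `predict(tile)` contract, and training data can be exported in the
polygon label-text format with a dataset YAML.

**Evaluation.** Mask IoU, greedy confidence-ordered matching,
precision/recall/F1, all-point-interpolated AP and mAP@0.5–0.95, and a
confusion matrix with a background row/column.

**SIMS corrections.** Non-paralyzable dead-time correction
`N = N_obs / (1 − N_obs·τ/t_dwell)` (τ default 44 ns, dwell 5 ms) per
plane, FFT cross-correlation drift estimation between planes, and
coverage-masked accumulation.

**Registration.** Closed-form least-squares similarity transform
(scale, rotation, translation; no reflection) from anchor-point CSVs or
from automatically paired nucleus blobs; nearest-neighbor mask warping
into the SIMS frame.

**Turnover kinetics.** Per-ROI enrichment `R = Σ ¹²C¹⁵N / Σ ¹²C¹⁴N`
(sum-then-divide), assembled over chase times and fitted with

    E(t) = E_nat + (E0 − E_nat) · 2^(−t / t_half)

by nonlinear least squares (`E_nat` fixed at 0.0037 natural abundance by
default, or fitted), with SEMs from the parameter covariance and
independent *t*-tests (Welch by default) for group contrasts.

**Synthetic ground truth.** A phantom generator produces EM-like images
with known instance masks and matched Poisson ion stacks with known
half-lives, drift, dead-time deflation and EM→SIMS transform, so the whole
chain is testable end to end without instrument data.

## Worked example

Simulate a full pulse–chase study (six organelle classes, chase times
0–96 h, Poisson counts, drift, dead time, a known EM→SIMS transform),
run every stage, and fit per-class half-lives:

```r
library(simscorr)

ion_spec <- ion_phantom_spec(
  t_half = c(nucleolus = 16.4, mitochondria = 21.5, ER = 19.2,
             Golgi = 16.4, vacuoles = 20.0, vesicles = 76.2),  # true values, h
  sims_shape = c(192L, 192L),
  em_to_sims = similarity_transform(scale = 0.6, theta = 0.1, tx = 12, ty = 6))

study <- run_phantom_study(seed = 1, ion_spec = ion_spec)
print(study$fits, digits = 3)
#>          class t_half t_half_sem     e0      rss n_points
#> 1    nucleolus   16.6      0.153 0.0500 4.62e-07        9
#> 2 mitochondria   21.3      0.382 0.0501 3.63e-05       34
#> 3           ER   17.4      0.410 0.0524 2.74e-05       24
#> 4        Golgi   16.5      0.354 0.0499 1.18e-05       17
#> 5     vacuoles   19.3      0.452 0.0513 2.72e-05       24
#> 6     vesicles   77.2      2.774 0.0497 2.08e-04       52
```

Each row is one organelle class: `t_half` is the fitted half-life in
hours (compare the true values above — all within a few percent under
counting noise), `t_half_sem` its standard error, `e0` the fitted initial
enrichment, and `n_points` the number of per-ROI measurements pooled
across the five chase times.

A noiseless round trip is exact:

```r
tt <- c(0, 12, 24, 48, 96)
fit_decay(data.frame(chase_time = tt, ratio = enrichment_decay(tt, 21.5, 0.05)))
#> <decay_fit> t1/2 = 21.5 +/- 5.8e-15 h, E0 = 0.05, E_nat = 0.0037 (fixed), n = 5, RSS = 1.03e-34
```

And the multi-pass tiling offsets for the default frame:

```r
pass_offsets(640, 5)
#> [1]   0 128 256 384 512
```

The file-based pipeline runs the same chain from a YAML config over a
study directory (`simulate_study()` writes one), producing
`measurements.csv`, `fits.csv`, per-image artifacts and a reproducibility
manifest:

```r
simulate_study("study", shared_phantom = TRUE)
run_pipeline(default_pipeline_config("study"), "results_dir")
```

A command-line launcher with subcommands (`simulate`, `preprocess`,
`segment`, `assemble`, `evaluate`, `sims-correct`, `register`, `quantify`,
`fit`, `compare`, `run`) is installed at `cli/simscorr` inside the
package directory.

## Documentation

See the methods vignette (`vignettes/simscorr-methods.Rmd`) for the model,
parameter defaults and units, the design decisions behind the merge rule,
perimeter estimator, registration and baseline handling, and an explicit
account of what the synthetic phantoms do and do not emulate.
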