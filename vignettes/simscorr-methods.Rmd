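---
title: "Methods: correlative EM/NanoSIMS analysis with simscorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlative EM/NanoSIMS analysis with simscorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simscorr)
```

# The problem

Correlative transmission electron microscopy (EM) and NanoSIMS imaging
pairs nanometer-scale cell morphology with per-pixel ion counts. To read
chemistry per organelle one must (i) segment organelle instances on the EM
image, (ii) map those masks onto the SIMS raster, which has its own
translation, rotation and pixel size, and (iii) extract corrected ion-count
ratios per instance. Doing this by hand is slow and subjective; `simscorr`
implements the full automated chain plus a synthetic world in which every
stage has known ground truth.

The headline application is pulse–chase protein turnover: cells incorporate
a ^15^N-labeled amino acid during a pulse, the label decays during the
chase, and the per-organelle ^15^N enrichment ratio
$R = {}^{12}C^{15}N^- / {}^{12}C^{14}N^-$ declines from its initial value
toward natural abundance.

# The decay model

We parameterize first-order label loss directly in terms of a half-life
$T$ (hours):

$$E(t) = E_{nat} + (E_0 - E_{nat})\, 2^{-t/T}.$$

* `e0` — enrichment at chase time 0 (set by the pulse). Default 0.05,
  a realistic bulk-protein enrichment after a two-day amino-acid pulse.
* `e_nat` — the asymptote. Default 0.0037, the natural ^15^N/^14^N
  abundance. Source material may use an unlabeled control group instead;
  `fit_decay()` therefore accepts any fixed baseline, or can fit it as a
  third parameter (`fix_baseline = FALSE`, needing ≥ 4 chase times).
* `t_half` — the quantity of interest.

`fit_decay()` runs nonlinear least squares over replicate per-ROI
measurements. Start values come from a log-linear regression of the
baseline-subtracted per-time means, so noiseless model data start at the
exact solution; the optimizer uses a scale offset in its convergence test
so exact (zero-residual) fits converge rather than error. A series whose
enrichment is indistinguishable from the baseline is rejected with an
explicit "no decay signal" diagnostic: a half-life is meaningless when
$E_0 - E_{nat} \approx 0$. The half-life standard error comes from the NLS
parameter covariance; the replicate unit is the ROI.

Group contrasts (`compare_groups()`) use an independent two-sample
*t*-test, Welch by default because per-organelle variance differs between
cell states; the pooled-variance test is available via `welch = FALSE`.
Stars follow the usual coding (\*, \*\*, \*\*\* at 0.05, 0.01, 0.001).

# Tiled multi-pass segmentation

Detector backends consume fixed `frame × frame` tiles (default 640 px, a
common network input size). Down-scaling a mega-image to one frame destroys
the morphology, so the image is reflect-padded and cut into disjoint tiles
instead — and because tiling truncates instances at tile borders, the grid
is applied `n_passes` times with origins shifted by `frame / n_passes`
pixels on both axes (`pass_offsets(640, 5)` gives 0, 128, 256, 384, 512).
An instance cut by one pass's boundary is interior to another pass.
Choices made here:

* **Reflect padding**, not constant: constant pads create artificial edges
  at tile borders that segmenters detect.
* **Offsets on both axes.** A single offset value per pass is applied to
  rows and columns alike; this is an interpretation (one scalar per pass),
  recorded here because a one-axis shift would leave the other axis's
  boundaries fixed across passes.
* Coordinates are 1-based (row, col) half-open tile extents internally, as
  is idiomatic in R; exported polygon labels use the 0-based normalized
  convention of the label-file format.

Per-pass detections are compiled by `merge_passes()`: same-class
detections are linked at mask IoU ≥ `iou_link` (transitive closure),
groups seen by fewer than `min_support` distinct passes are dropped, and
surviving groups take the **union** of member masks — offsets exist
precisely to recover pixels truncated in some passes. Defaults
`iou_link = 0.5` (the usual IoU-threshold convention) and
`min_support = 2` of 5: a boundary-truncated single-pass fragment is
rejected, any two-pass consensus survives. The compilation rule in the
source workflow is not specified beyond "compiled into a single mask";
support-threshold union is this package's interpretation and both knobs
are configuration. Remaining same-class overlaps are resolved by
confidence, with ties broken by support and then area so that a multi-pass
consensus instance always beats its own fragments.

Morphological filtering then applies per-class rules: a minimum area
(default 20 px², removes contour noise) and, for the circular classes
(vesicles, vacuoles), a minimum circularity $4\pi A / P^2$ (default 0.7)
that removes partially detected instances. Perimeter is the Freeman
chain-code length of the Moore-traced external boundary (axial step 1,
diagonal $\sqrt 2$); on canonical rasterized shapes this gives
circularity ≈ 0.91 for a large disk, ≈ 0.80 for a square (continuous
value $\pi/4$), and ≈ 0.03 for a 1-px line, so disks and truncated disks
separate cleanly.

# Backends

The real detector in this workflow is a trained neural instance
segmentation network. Its weights are not distributable and its training
requires GPU time and annotated EM data, so the package defines a backend
**contract** — `predict(tile)` returning class, mask, confidence — and
ships a deterministic classical `toy_backend()` that thresholds the
phantom's class intensity bands and labels connected components. Any
adapter honoring the contract plugs into `run_pass()` unchanged; the
pipeline's correctness is independent of the detector choice, which is
exactly what the test suite establishes. Training-data export
(`masks_to_labels()`, `build_dataset()`) writes the polygon label text
format and `{train,val,test}` layout with a dataset YAML (6 classes) that
detector tooling consumes; only the external contour of each mask is
exported (holes are not representable in that format).

# Evaluation

`simscorr` scores predictions with the standard detection metrics: mask
IoU; greedy confidence-ordered matching at an IoU threshold (Hungarian
assignment is deliberately *not* used in the implementation — the greedy
convention matches detector tooling — but brute-force assignment serves as
the oracle in tests); precision/recall/F1 with F1 = 0 when both are 0;
average precision by descending-confidence sweep with **all-point
interpolation** (the precision envelope), the modern convention, recorded
here because older 11-point interpolation gives different values;
mAP@0.5–0.95 averaged over the 0.50:0.05:0.95 threshold ladder and then
over classes with ≥ 1 truth instance; and a confusion matrix with a
background row/column (columns = true classes, rows = predictions,
columns normalized to relative frequencies). A "loss" reporter is provided
as 1 − recall with a flag to return recall instead; whether a recall/loss
curve means 1 − recall or a training loss is ambiguous in common usage, so
the definition is explicit here.

# Ion stacks and corrections

A NanoSIMS acquisition rasters the field 4–5 times (planes) at ~5 ms dwell
per pixel. Two corrections precede quantification:

* **Dead time.** Counting detectors are blind for a fixed interval τ after
  each ion; observed counts deflate nonlinearly. We use the
  non-paralyzable model $N = N_{obs} / (1 - N_{obs}\,\tau / t_{dwell})$,
  applied per plane *before* accumulation (the correction is nonlinear, so
  order matters). τ defaults to 44 ns, typical for this instrument class;
  it is configurable and recorded in output metadata because the true
  value is instrument-specific. Saturated pixels raise an error naming the
  offending count.
* **Drift.** Stage/beam drift shifts successive planes. Integer-pixel
  shifts are estimated per plane by FFT cross-correlation against a
  reference plane (mean-subtracted; flat planes get zero shift with a
  warning), applied inversely, and the planes summed. Pixels not covered
  by every plane are masked `NA`. Sub-pixel drift is out of scope; the
  synthetic generator injects integer shifts so recovery is exact.

Drift is estimated on the high-count ^12^C^14^N image and applied to both
species, keeping the ratio aligned.

# Registration

The EM→SIMS mapping is a 4-DOF similarity transform (isotropic scale,
rotation, translation) — the three manipulations an operator performs when
overlaying the modalities; no shear, and reflections are excluded by
constraining the determinant positive in the fit. `fit_similarity()` is
the closed-form least-squares (Umeyama) solution on anchor-point pairs;
anchors come from a CSV file (replacing interactive overlay tools, which
are out of scope) or from `auto_anchor_nuclei()`, which exploits the fact
that dense nuclear bodies are dark in EM and CN⁻-bright in SIMS, pairs the
largest blobs of each modality by enumerating assignments (≤ 6! = 720)
and keeps the lowest-residual fit. Masks are warped by inverse mapping
with nearest-neighbor interpolation (masks stay binary; area scales as
$s^2$ within ~5% discretization for instances ≥ 100 px); intensity images
use bilinear. The EM→SIMS direction is the package's convention; the
inverse is always available (`invert_transform()`).

# Quantification

Per-ROI enrichment is **sum-then-divide**: $R = \sum N_{15} / \sum N_{14}$
over mask pixels, which equals the count-weighted mean of pixel ratios and
is far more stable than averaging per-pixel ratios at low counts. ROIs
with zero ^14^N counts are excluded with a warning. Multipoint
("click-tool") extraction sums counts over a disk (default radius 2 px)
around each coordinate; on phantoms with intra-ROI gradients the point
ratios scatter around the unique mask ratio, demonstrating why full-mask
extraction is preferred when signal heterogeneity exists across an ROI.

# The synthetic world

`make_em_phantom()` places rasterized rotated ellipses (disks for
vesicles/vacuoles) of six organelle classes on a noisy background, by
rejection sampling with a 2-px exclusion margin — masks are connected,
mutually disjoint, and each class paints a distinct gray-level band
(centers 0.10 … 0.70, halfwidth 0.05, background 0.86). The class↔band
mapping is fixed so the toy backend is parameter-free in tests.
`make_ion_stack()` maps every SIMS pixel through the inverse of a known
EM→SIMS transform, assigns the in-ROI expected ratio from the decay model
(per-class half-lives) and the out-of-ROI baseline, modulates expected
^14^N counts by per-class density factors (nucleolus 2.0 by default —
protein-dense structures emit more CN⁻, which is also what makes automatic
nucleus anchoring possible), shifts each plane by its drift vector,
Poisson-samples counts (or returns expectations in noiseless mode), and —
when τ > 0 — deflates counts by the exact inverse of the dead-time
correction, so the correction provably recovers them.

Defaults state the studied world: chase times 0, 12, 24, 48, 96 h; 4
planes; 5 ms dwell; ~50 expected ^14^N counts/pixel/plane; ±1 px
inter-plane drift; E₀ = 0.05, E_nat = 0.0037.

What the phantom does **not** emulate — so what a green test does not
establish: realistic EM texture (membranes, cristae — the bands are
separable by construction, so toy-backend accuracy says nothing about a
real detector's accuracy on real EM); smooth gray-level histograms
(organelle pixels occupy discrete bands, so quantile histogram matching
between *different* phantoms can relocate whole bands when area fractions
differ — the file-based pipeline therefore exposes `preprocess:
match|none`, and phantom studies either reuse one cell field per chase
time, making matching the identity, or disable it; on real EM the
assumption holds and matching is the documented default); detector dead
time beyond the non-paralyzable model; sub-pixel drift; and cell-division
dilution of label, which is a biological confounder outside the model.

# Numerical and degenerate-input policy

* Histogram matching requires a non-constant reference (error, not
  pass-through): matching to a constant image is not a contrast transform.
* IoU of two empty masks is an error (undefined), not 0.
* `pass_offsets()` requires `n_passes` to divide the frame and lists valid
  counts in its error.
* Confusion-matrix columns are normalized per true class; the background
  column is normalized over the spurious predictions it contains.
* All generators are seeded; identical spec + seed gives byte-identical
  output, and generator seeds are derived so each chase time has an
  independent stream.
* `fit_decay` needs ≥ 3 distinct chase times (4 when the baseline is
  free), positive ratios, and a detectable decay signal.

# End-to-end validation

`run_phantom_study()` chains every stage in memory: phantom → multi-pass
toy segmentation → merge + filter → anchor-based registration →
dead-time/drift correction → warped-mask enrichment → per-class decay
fits. With Poisson counting noise, known drift and transform, and true
half-lives {16.4, 21.5, 76.2} h, the study recovers all three within 10%
relative error in ≥ 95% of seeds (the acceptance suite runs 20). The
file-based `run_pipeline()` covers the same chain from a YAML config over
a study directory, writing every intermediate artifact and a manifest
(config hash, versions, seeds, per-pass offsets, timings); identical
configs reproduce identical result CSVs, and per-image artifacts on disk
can be reused (`resume = TRUE`).

# Known limitations

* The toy backend reads the phantom's band code; it is a contract fixture,
  not an EM segmenter.
* Boundary tracing assumes instances whose external boundary visits the
  trace start once (true for the convex-ish phantom shapes); pathological
  masks may yield truncated polygons in label export.
* Integer-pixel drift only; similarity (not affine or deformable)
  registration only.
* Single-exponential decay only; no correction for label dilution by cell
  division.
* Ion stacks are ingested as open formats (per-plane text matrices + JSON
  sidecar, PNG for EM); vendor raw files must be converted upstream.
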