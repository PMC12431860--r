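---
title: "Quantifying aggrephagy: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aggrephagy: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggrequant)
```

## The measurement problem

Aggrephagy — the selective autophagic clearance of protein aggregates — is
commonly read out with a tandem-fluorophore reporter: an aggregation-prone
construct carrying both mCherry and GFP. In the cytosol an aggregate is
positive in both channels ("white" in an overlay); once delivered to the
acidic lysosome the GFP moiety is quenched and the punctum turns red-only.
The fraction of red aggregate area that is still green-positive therefore
tracks the undegraded pool, and its decay over a time-lapse movie measures
lysosomal flux. Around this central readout sit several companion
measurements: puncta counts and sizes over time (and their area under the
curve for aggregation-prone cargo such as polyQ-expanded huntingtin),
ROI-based protein recruitment, single-molecule localization microscopy
(SMLM) of autophagy-receptor nanoclusters on aggregate surfaces, the
grey-value spread of electron-tomography cross-sections as a proxy for
aggregate compaction, and FRAP as a probe of molecular mobility inside
inclusions.

`aggrequant` implements each of these quantifications as a tested function,
plus generators that synthesize every input with known ground truth, so the
estimators can be validated end to end.

## Puncta segmentation

`tophat_segment()` reproduces an automated live-cell analyser
configuration: a white top-hat transform (image minus its morphological
opening) with a disc structuring element of radius 10 µm for the green and
100 µm for the red channel, followed by a relative threshold of 0.7. The
top-hat removes any structure larger than the disc, so flat fields and
smooth illumination gradients segment to nothing, and adding a constant to
the image changes nothing.

Three implementation choices matter:

* **Border handling.** Grayscale morphology needs values beyond the image
  border; zero-padding manufactures bright top-hat artifacts up to two
  radii deep. We pad by edge replication over that full depth, which makes
  constants and ramps segment to exactly nothing at the price of a larger
  transform (the dominant cost of the movie pipeline).
* **Denoising before thresholding.** The instrument's "colour unit"
  threshold of 0.7 is applied here to the top-hat response min–max
  normalized per image. On shot-noise-limited images the raw per-image
  maximum is a single-pixel Poisson extreme, which drags the relative
  threshold above every real punctum. A light Gaussian smoothing of the
  top-hat response (`smooth_sigma_px`, default 0.7 px) restores a stable
  maximum; it is the one step added relative to the bare
  top-hat → normalize → threshold chain, and can be disabled.
* **Connectivity.** Components are 8-connected, and objects below
  `min_area_px` (default 3) are discarded.

The relative (per-image) normalization assumes the brightest punctum in
each frame has a comparable peak; this holds for the reporter system
(uniform labelling) but means a frame with *no* true puncta segments noise.
Downstream, the white *fraction* is robust to this because stray green
specks rarely intersect red objects.

The white readout itself is area-based: `white_overlap()` intersects the
two masks and divides by the red area, following the convention that the
red channel defines the aggregate pool. An object-level classification
(`classify_puncta_colour()`, white if ≥ 50% of a red object's pixels are
green-positive) is provided for per-punctum statistics, since an area
ratio has no per-object analogue.

## Degradation kinetics

`degradation_rate()` converts the white-fraction series to natural logs and
reports minus the unweighted least-squares slope — deliberately the plain
"SLOPE of ln(values)" estimator, so results are comparable with
spreadsheet-based analyses. It is exact on noiseless exponentials and
invariant to rescaling the series (fraction vs percentage). Two defaults
had to be fixed where common practice is silent:

* the **fit window** starts at the first point below 95% of the series
  maximum (skipping any initial plateau) and ends at the last point above
  the **log floor**, default `1e-3 ×` the series maximum, below which
  values are treated as numerically zero and excluded (with a logged
  count);
* both are overridable per call.

A note on attainable precision: with `n` aggregates converting
independently at rate *k* over a movie of length *T*, the information in
the entire white-fraction curve about *k* is that of `n` censored
exponential waiting times, bounding any estimator's standard deviation
below by `k / sqrt(n (1 - exp(-kT)))` — about 7.4% relative at `n = 200`,
`k = 0.1 h⁻¹`, `T = 24 h`. Per-movie estimates at that scale scatter
accordingly; the estimator is unbiased (verified to within a few percent
across `k ∈ {0.05, 0.1, 0.2} h⁻¹` in the test suite), and precision is
bought with more aggregates, not a different fit.

`auc()` is the trapezoidal integral of a puncta-count (or any) time
course, additive over adjacent intervals. `frap_normalize()` divides a
FRAP trace by the mean of its pre-bleach frames, making the post-bleach
plateau directly interpretable as the recovered fraction.

## SMLM receptor clustering

The cluster statistic is the one used for receptor nanodomains on
aggregates: within each aggregate ROI, compute the mean nearest-neighbour
distance d̄ of all molecules, set the density radius `r = 5 d̄`, and give
each molecule a local density `D` = number of *other* molecules within `r`
(closed ball — ties at exactly `r` count). Molecules with `D > 40` are
cluster material. Because `r` scales with d̄, the whole analysis is
scale-equivariant: rescaling all coordinates leaves every `D`, every
membership and every cluster count unchanged.

The published procedure applies both the `D > 40` rule and a
density-based clustering step without fixing their composition or the
DBSCAN parameters; here clusters are defined as connected components of
the thresholded molecules linked at `link_radius = r`, kept if they have
at least `min_members = 3` molecules — a DBSCAN-equivalent on the
thresholded set with all three knobs in the configuration. The density
threshold 40 is tied to the acquisition density of the original
experiments and is a config default, not a constant. Per-cluster
localization density uses the convex-hull area of the members; clusters
with a degenerate hull report `NA` density rather than a fabricated one.
Aggregates enter the analysis only with ≥ 100 localizations (the published
inclusion bound of 100, which its source prints as "<100" — almost
certainly a typo for ">100"; both a minimum and a maximum are exposed).

Upstream of clustering, the raw-movie branch mirrors a standard SMLM
chain: `temporal_median_filter()` (running per-pixel temporal median,
robust to sparse blinking), `gaussian_localize()` (local maxima refined by
least-squares 2-D Gaussian fits; the localization error is the standard
error of the fitted centre, floored at 1 nm), `render_reconstruction()`
(each molecule as a Gaussian of s.d. equal to its localization error;
kernels are truncated at 4σ and normalized to unit *sum*, which conserves
the localization count exactly and avoids the aliasing of an analytic
normalization when σ is below the render pixel), and `drift_correct()`
(block reconstructions registered to the first block by the
cross-correlation peak with quadratic sub-pixel refinement; shifts are
applied per block, i.e. a piecewise-constant drift model, which is exact
for step drifts and idempotent; for the intermediate reconstructions the
kernel is floored at 1.5 render pixels because a correlation peak narrower
than the grid biases the quadratic interpolation).

## Compaction from cross-section profiles

`extract_profile()` samples grey values by bilinear interpolation along a
line segment (user-supplied, or a seeded `random_chord()` within a mask —
the original sections were placed by hand, so exact placement is
irreproducible by design). `normalized_spread()` divides every sample by
its aggregate's mean grey value, pools normalized values per condition,
histograms them with equal-width bins over a range shared across
conditions (`[0, max]`, default 20 bins), and reports the **standard
deviation of the normalized values** as a scalar spread. The published
comparison is the histogram shape; the SD is added because a scalar is
needed for testing and cross-condition ratios, and for per-aggregate
normalized data it estimates exactly the within-aggregate coefficient of
variation.

## Synthetic data: what it emulates, what it does not

The generators define the study conditions used throughout the tests:

* **Reporter movies** (`simulate_aggrephagy_timelapse()`): aggregates as
  2-D Gaussian blobs (σ = radius/2) of equal peak brightness on a
  200 × 200 px field at 1 µm/px, radii uniform in 2.5–3.5 µm, placed with
  a hard-core separation of twice the largest radius (puncta are distinct
  objects). Quenching is a one-way dual → red-only transition with
  exponential waiting time (rate `k_deg`); optional symmetric
  fragmentation conserves area and inherits the parent's quenching clock.
  Camera noise is Poisson shot noise (background 20, peak 300 photons)
  plus Gaussian read noise (SD 3) — a standard camera model chosen in the
  absence of a published one. The ground-truth white fraction is the
  area-weighted dual fraction computed from the noiseless footprints, so
  with no fragmentation its expectation is exactly `exp(-k_deg t)`. Not
  modelled: partial acidification, photobleaching, cell movement,
  coalescence of independent aggregates, or focus drift — passing tests
  show estimator correctness under the stated model, not robustness to
  those effects.
* **SMLM localizations** (`simulate_smlm_localizations()`): per aggregate,
  `round(f·n)` molecules in isotropic Gaussian clusters (centres placed
  with a minimum separation, default 16 cluster-σ, i.e. clearly beyond the
  linking radius — clusters closer than `r` merge by construction and are
  not "well separated" for this statistic) and the rest uniform on the
  footprint; all coordinates jittered by the localization error, truncated
  at 4σ so no molecule leaves the footprint by more than 4× the error.
  Cluster membership is multinomial by default or exactly equal on
  request.
* **Raw SMLM movies** (`simulate_raw_smlm_frames()`): Bernoulli blinking,
  Gaussian PSF spots, a smooth (optionally drifting) background, Poisson
  noise, and an optional recorded step drift between movie halves.
* **Profiles** (`simulate_profile()`): zero-truncated Gaussian grey values
  whose parent parameters are moment-matched so the *truncated*
  distribution hits the requested mean and CV (naive truncation would
  shrink a CV of 0.5 by several percent).
* **FRAP** (`simulate_frap()`): the single-exponential recovery closed
  form, 80 frames every 10 s with two pre-bleach frames by default.

All generators are deterministic given `seed`.

## Problem sizes and numerical choices

The test suite validates the movie pipeline at 200 aggregates × 49 frames
(20 seeds for the acceptance run) and the bias of the rate estimator at
100 aggregates × 13 frames × 5 seeds per rate; cluster recovery uses 100
seeds of 250-localization aggregates; oracle-equivalence checks run at
1,000 points against literal O(n²) double loops. Distances use plain
Euclidean double arithmetic on full distance matrices (fine to ~20k
points); ties at the density radius are counted as inside; histograms use
right-closed bins including the lowest edge. Degenerate inputs error
early and explicitly: empty red masks (white fraction 0 with a warning),
aggregates with fewer than two molecules, zero-mean profiles, fit windows
with fewer than three usable points.

## Known limitations

* The segmentation is intensity-based and assumes the brightest object in
  a frame is a genuine punctum; frames with no true signal yield noise
  masks (harmless for the white fraction, not for absolute counts).
* The per-image relative threshold reproduces the instrument's behaviour
  only up to its uncalibrated "colour unit" scale; absolute comparability
  across very differently exposed experiments requires fixing the
  normalization scale per experiment.
* `local_density()`/`mean_nn_distance()` are O(n²); SMLM tables far beyond
  ~20,000 localizations per aggregate would need a spatial index.
* The drift model is piecewise-constant per block; smooth drift is
  approximated by increasing `n_blocks`.
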