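# aggrequant

Quantification pipeline for fluorescence-based **aggrephagy** assays — the
selective autophagic clearance of protein aggregates — built around a
tandem mCherry–GFP aggregation reporter. An aggregate is "white"
(green + red) in the cytosol; on delivery to the lysosome the GFP is
quenched by the acidic pH and the punctum turns red-only, so the decay of
the white area fraction measures degradative flux.

The package implements, as tested reusable functions:

* **Puncta segmentation** — white top-hat transform with disc structuring
  elements (10 µm green / 100 µm red), relative threshold 0.7,
  8-connected components (`tophat_segment()`, `detect_puncta()`,
  `white_overlap()`), plus object colocalization, ROI intensity fold
  changes and GFP area fractions.
* **Kinetics** — degradation rate as −slope of ln(white fraction) vs time
  (`degradation_rate()`), trapezoidal AUC of puncta-count time courses
  (`auc()`), and FRAP pre-bleach normalization (`frap_normalize()`).
* **SMLM receptor clustering** — for each molecule on an aggregate, the
  local density *D* = number of other localizations within
  *r* = 5 × (mean nearest-neighbour distance of the aggregate's
  molecules); molecules with *D* > 40 form clusters (connected components
  at linking radius *r*, ≥ 3 members). Includes temporal median
  background removal, Gaussian spot localization, reconstruction
  rendering and cross-correlation drift correction
  (`aggregate_metrics()`, `local_density()`, `drift_correct()`, ...).
* **Compaction** — grey-value cross-section profiles normalized to each
  aggregate's mean; the SD of normalized values (≈ within-aggregate CV)
  quantifies loose vs compact packing (`extract_profile()`,
  `normalized_spread()`).
* **Synthetic data with ground truth** for every input: two-channel
  reporter movies with exponential quenching at rate `k_deg`
  (`simulate_aggrephagy_timelapse()`), clustered SMLM localizations
  (`simulate_smlm_localizations()`), raw blinking movies
  (`simulate_raw_smlm_frames()`), cross-section profiles
  (`simulate_profile()`) and FRAP traces (`simulate_frap()`).

See `vignettes/aggrequant-methods.Rmd` for the models, parameter choices
and limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R`, then `02`–`05`). Script 01
simulates a 24 h movie of 200 aggregates quenching at 0.1 h⁻¹; script 02
segments it and fits the rate:

```
White fraction: measured 0.96 -> 0.15 (truth 1.00 -> 0.15)
Degradation rate: 0.0749 /h (R^2 = 0.989, window 2..49)
  generating rate 0.1000 /h; this cohort's realized (truth-curve) rate 0.0786 /h
Red puncta per frame: median 192; AUC over 0-24 h: 4614.2
```

The fitted rate tracks the *realized* decay of this finite cohort (one
200-aggregate field; the conversion times of this particular seed decay
at 0.079 h⁻¹) — with 200 aggregates any estimator carries ~7% relative
sampling error. Script 03 prints the receptor-cluster contrast:

```
  clustered  density 314 /um^2, clusters/aggregate 3.00, in-cluster density 6799 /um^2
  dispersed  density 312 /um^2, clusters/aggregate 0.00, no clusters
```

and script 04 the compaction readout (spread 0.504 for the loose vs 0.049
for the compact condition — a 10× contrast at matched overall density).

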