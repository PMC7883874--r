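---
title: "Estimating legume-grass biomass and nitrogen fixation by sensor fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating legume-grass biomass and nitrogen fixation by sensor fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionfield)
```

## The problem

Legume-grass leys are a central nitrogen source on organically managed
farms: the legumes fix atmospheric N, and both total biomass (fresh matter
FM, dry matter DM, t ha⁻¹) and the fixed nitrogen (N_Fix, kg ha⁻¹) drive
management decisions. Measuring them destructively is slow, so this
package estimates them from two non-destructive sensor streams:

* **structural**: terrestrial laser scans, converted to a crop surface
  height (CSH) raster, `CSH = DSM − DEM`, at 5 cm resolution, summarised
  per plot by 15 distributional metrics (mean, min, max, median, variance,
  sd, range, mode, Fisher–Pearson skewness, excess kurtosis, canopy height
  relief `(mean − min)/(max − min)`, and the 25/75/90/95 percentiles);
* **spectral**: four-band (green, red, red edge, NIR) reflectance rasters
  at 4.5 cm, summarised by zonal band means and 13 vegetation indices;
* **textural**: eight Haralick features (energy, entropy, correlation,
  inverse difference moment, inertia, cluster shade, cluster prominence,
  Haralick correlation) of sliding-window gray-level co-occurrence
  matrices, computed on the mean-CSH raster and on each band, then
  averaged per plot. Texture captures the horizontal heterogeneity that
  plot-mean heights and reflectances ignore, which matters for botanically
  diverse swards.

Three predictor variants are compared: **CSH** (15 height metrics + 8
height-texture features, 23 predictors), **MS** (4 band means + 13 indices
+ 32 band-texture features, 49) and **Fusion** (their union, 72).

N fixation uses the difference method: `N_Fix = N_L − N_R`, the N amount
(DM × 10 × N%) of the legume-bearing stand minus that of a paired
non-fixing pure-grass reference. The reference is the pure-grass plot of
the same mixture family in the same block; if that plot is missing for a
harvest, the mean of the remaining reference replicates is used. Negative
values are retained and flagged — under the difference method they are
meaningful. Pure-grass plots never receive an N_Fix value.

## The synthetic experiment

Field data of this kind are rarely publicly deposited, so the package
ships a generator, `simulate_experiment()`, whose **defaults are the
study conditions**: 24 plots of 1.5 × 12 m (six
treatments — clover-grass CG, lucerne-grass LG, their pure legume stands
L_CG/L_LG and pure grass stands G_CG/G_LG — in four randomised complete
blocks), two seasons of three harvests, a 5 cm height grid and a 4.5 cm
spectral grid, and four plot-harvests excluded at the final harvest of the
second season. That leaves exactly 140 FM/DM samples, and — because two
of the excluded plots are legume-bearing — 94 N_Fix samples.

Generator mechanics, and the choices behind them:

* **Latent growth factor.** Each plot-harvest draws a lognormal factor
  `g = exp(N(0, cv²))` (cv = 0.08) that multiplies both its biomass and
  (damped, `g^0.7`) its canopy height, so structural predictors carry
  genuine signal about yield rather than only treatment identity.
* **Canopy profile.** Point heights follow a Beta(2, 5) distribution
  scaled to `[0, 3.5 × target]`, giving the right-skewed profile of a real
  sward while keeping the sample mean equal to the target mean height.
  Ground returns appear where the canopy leaves gaps; canopy cover
  saturates with biomass as `FM/(FM + 5)`.
* **Within-plot heterogeneity.** A Gaussian random field (FFT-filtered
  white noise) with a treatment-specific correlation length (0.15–0.45 m)
  modulates heights and reflectance. Mixtures get larger field amplitude
  than pure stands, so texture features genuinely discriminate treatments.
* **Reflectance.** Per-plot band levels are saturating functions of DM
  (NIR rises, red falls), pathways carry bare-soil reflectance, and the
  correlated noise field rides on top. Values are clipped to [0, 1] with a
  5% clipping budget per plot.
* **Year effects.** Season one is a drought year: legume growth × 0.6
  while mature grass grows tall (height × 1.3) with unchanged biomass.
  In season two the unfertilised grass suffers nutrient deficiency
  (growth × 0.7). This reproduces the qualitative pattern that mixtures
  and legumes yield more in the regular year while pure grass shows the
  opposite, and it decorrelates height from biomass exactly where sensor
  fusion should help.
* **Calibration.** Treatment base values (per-harvest FM 7–25 t ha⁻¹, DM
  content 0.14–0.22, N concentration 1.5% grass / 3.3–3.5% legumes) were
  calibrated once so that annual sums over complete plot-years fall inside
  the observed field envelopes (FM 10.36–103.94 t ha⁻¹, N_Fix
  59.73–369.24 kg ha⁻¹). Annual envelopes are evaluated on complete
  (three-harvest) plot-years only, since excluded plot-harvests leave
  truncated annual sums that no field report would tabulate.

What the generator does **not** emulate: registration and geo-referencing
error between sensors, radiometric calibration drift, species-level
spectra, weather time series, or saturation artefacts of real multispectral
sensors. Consequently the synthetic scenes are *easier* than field data —
validation accuracies here (median rRMSEP roughly 3–5%) are far better
than any field campaign would achieve, and passing tests demonstrate the
correctness and internal consistency of the pipeline, not field-level
accuracy.

## Texture numerics

`texture_image()` computes a GLCM per pixel over a `(2r+1)²` window
(default radius 2, i.e. 5 × 5) with a single `(0, 1)` offset and symmetric
pair counting, after linear quantization to 8 gray levels — the defaults
of the common remote-sensing toolbox lineage; all are configurable.
Implementation is vectorised: the G² co-occurrence indicator planes are
box-summed with summed-area tables, so cost is linear in pixel count, and
a brute-force per-window recomputation is used as the test oracle. Edge
pixels use the truncated in-bounds window; nodata pixels are excluded from
pairs. Entropy is in bits (base 2). The CSH raster is quantized over
`[0, p99.9]` of the scene's height values so a single outlier cannot
collapse the bins; band crops are quantized over their own range. The
`haralick_correlation` feature follows the marginal-row-sum convention of
that toolbox lineage, `(Σ ij p − μ_t²)/σ_t²` with `μ_t, σ_t` the mean and
population sd of the G marginal row sums; the textbook index-weighted form
(identical to the `correlation` feature) is available via
`hc_variant = "f3"`. Degenerate zero-variance cases return 0 with a
warning.

## Selection and validation

Variable selection is the three-step procedure: (1) *thresholding* — mean
and sd of permutation importance over 50 forests; a regression tree fitted
to sd versus rank supplies the threshold (its minimum prediction), and
variables with lower mean importance are dropped (fallback: top ⌈√p⌉);
(2) *interpretation* — nested models over importance-ordered prefixes, 25
forests each; the smallest prefix within one sd of the minimum mean OOB
error wins; (3) *prediction* — a greedy forward pass keeping a variable
only when it lowers OOB error by more than the mean absolute fluctuation
of the post-interpretation OOB trace; the first variable is always kept.
All forest counts are exposed; forests are 500 trees with regression
`mtry = p/3`; ties in importance break by column name. Selection runs on
the full table before splitting, as is common in this workflow — a known
optimistic-bias source, acknowledged here; the selected sets are small so
the practical leakage is minor, and selection can equally be run on any
subset the user supplies.

Validation repeats a stratified 75/25 split (validation covers every year,
harvest and treatment margin) 100 times by default; each sample lands in
validation a median of ~25 times. Per split, `mtry` is tuned by 5-fold
cross-validation on the calibration rows over `⌈p/3⌉ ± 2` (clamped to
`[1, p]`; the often-quoted n/3 rule exceeds the predictor count after
selection, so the conventional p/3 default anchors the grid). Accuracy is
reported as `R²_val` and `rRMSEP = 100·RMSE/range(y)`. The R² centring
uses the observed-mean convention by default; the predicted-mean variant
(`center = "predicted"`) is available but makes R² incomparable across
models. Year effects on prediction quality use the normalised deviation
`(ŷ − y)/(ŷ + y)` per mixture, tested by Kruskal–Wallis plus Dunn's
pairwise z tests with tie correction and Holm adjustment, summarised by a
compact letter display.

## Problem sizes and determinism

Everything is deterministic given a single master seed: child seeds are
derived arithmetically for each plot, split, forest and tuning fold, and
forests run single-threaded. The shipped analyses use the full default
scene (140 samples); the variant comparison in the acceptance script runs
25 splits per variant for the FM response, selection recovery uses 20
seeded replicates of a 3-signal + 47-noise design at signal-to-noise 3,
the split-coverage study uses 100 seeds, and the year-effect size/power
study uses 1000 null and 100 shifted simulations with groups of 20
normalised deviations of sd 0.15 (the spread the default scene produces)
and a +0.2 shift. These sizes give stable Monte-Carlo estimates while
keeping a full run in minutes on one core.

## Degenerate inputs and edge rules

Cells are half-open intervals and a cell's value sits at its centre;
empty cells are nodata and propagate. Negative CSH (ground noise) clamps
to 0 and is counted. A flat canopy returns 0 for relief, skewness and
kurtosis with a warning; the mode of a continuous sample is the midpoint
of the most populated 1 cm bin. Zero vegetation-index denominators yield
`NA` with a warning, never an error. Constant responses, singleton strata,
zero observed ranges and empty zonal masks raise informative errors.

## A short worked run

A reduced configuration (two blocks, one season, one harvest) runs the
whole chain in seconds:

```{r, eval = FALSE}
cfg <- sim_config(seed = 11, n_replicates = 2, years = default_years()[2],
                  harvests_per_year = 1, point_density = 400,
                  ground_density = 700, exclusions = "none")
res <- run_pipeline(cfg, responses = "FM", variants = c("CSH", "Fusion"),
                    n_splits = 10, do_selection = FALSE)
res$summary
```

For the full study conditions use `sim_config(seed = 1)` and
`n_splits = 100`; `scripts/acceptance.R` is a ready-made driver.

## Known limitations

Plot polygons are axis-aligned rectangles (the experiment's layout); the
point-in-polygon test is general, but the destructive-strip trim assumes
the strip sits at the low-y plot end. The 13-index registry is a
documented default spanning the common index families and can be replaced
wholesale via `vi_registry()`. File interchange uses
plain-text formats (XYZ clouds, ESRI ASCII grids, GeoJSON, CSV); there is
no LAS/GeoTIFF writer. And, as above, synthetic accuracy should never be
quoted as an expectation for field data.
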