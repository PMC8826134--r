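---
title: "Modelling low-altitude flight and wind-turbine collision risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling low-altitude flight and wind-turbine collision risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Soaring raptors and wind turbines compete for the same airspace: the
updraught-rich band close to steep, sun-exposed terrain. A collision can
only happen where a bird actually flies within the rotor-swept zone —
conventionally the 0–200 m band above ground level (AGL). `rotorrisk`
implements a complete pipeline that turns raw GPS telemetry into a map of
the probability that a bird flies below that critical altitude, and then
into planning products: a binary critical-flight map held to 95%
sensitivity, a joint probability map (occurrence × low flight), and a
high-risk conflict map that restricts a 4-level potential-conflict surface
to the cells where low flight is predicted.

The pipeline has six stages, each a package module:

1. **synthetic world** (`world_config()`, `generate_dem()`,
   `generate_env_stack()`, `generate_tracks()`) — a fully synthetic study
   system with a *known* generating process, so every later stage can be
   tested against ground truth;
2. **track cleaning** (`clean_tracks()` and the individual filters);
3. **terrain predictors and encoding** (`build_env_stack()`,
   `extract_features()`, `fit_normalizer()`, `collinearity_screen()`);
4. **classifier** (`model_config()`, `train_network()`, `predict()`);
5. **evaluation** (`auc()`, `grid_search()`, `loo_bird_cv()`, `block_cv()`,
   `permutation_importance()`, `ice_pd()`);
6. **risk maps** (`bagging_train()`, `predict_raster()`,
   `aggregate_bagged()`, `threshold_at_sensitivity()`, `binarize()`,
   `joint_probability()`, `high_risk_intersect()`).

The numbered scripts under `analysis/` run these stages end to end and
write their tables and rasters under `results/`.

## The response and the classifier

Each cleaned GPS fix is labelled 1 if its AGL is strictly below the
critical altitude (200 m; a fix at exactly 200 m is class 0) and 0
otherwise. The classifier is a feedforward network: 22 inputs → hidden
layer 1 (ReLU) → inverted dropout → hidden layer 2 (ReLU) → one sigmoid
output, trained to minimise binary cross-entropy with Adam. The 22 inputs
are 10 one-hot land-cover indicators, 4 one-hot geology indicators, and 8
continuous predictors (eastness, northness, slope, slope unevenness, TPI,
ibex and chamois occurrence probability, wind speed at 100 m), z-scored
with mean and standard deviation computed **on the training split only**.
This column order is a package contract (`feature_names()`): generating
coefficient vectors and importance groups index into it.

Defaults (all overridable in `model_config()`):

| parameter | default | rationale |
|---|---|---|
| units1 / units2 | 256 / 32 | the architecture selected by the grid search protocol |
| dropout rate | 0.4 | selected jointly with the widths |
| hidden activation | ReLU | unobjectionable default for this depth; configurable |
| optimizer | Adam, lr 0.001, β₁ 0.9, β₂ 0.999, ε 1e-7 | the framework defaults this training protocol implies |
| batch size | 512 | large-data regime; one epoch = one shuffled pass |
| early stopping | patience 10 on validation AUC, strict improvement, best weights restored | "no increase for more than 10 epochs", with the common best-weights restoration |
| loss clipping | probabilities clipped to (1e-7, 1−1e-7) | numerical safety only |

The architecture search enumerates hidden widths 16, 32, 64, 128, 256,
512 in each layer independently and dropout 0.2–0.7 in steps of 0.1 — 216
configurations (`grid_configs(grid_spec())`), each trained on a fixed
70/30 split with early stopping and ranked by validation AUC. Whether the
70/30 split is drawn over fixes or stratified by bird was an open choice;
the default is a seeded random split over fixes, with
`split_train_val(by_bird = TRUE)` available, because fix-level splitting
matches the way the validation AUC is used for early stopping.

## Cleaning rules and their boundary conventions

The cleaning cascade applies, in order: completeness (both altitude and
instantaneous ground speed present), datum conversion (ellipsoidal heights
minus geoid undulation → MSL), AGL computation against the DEM, quality
culling, AGL plausibility, daylight, flight filter, region mask,
post-release exclusion, per-minute subsampling, and a per-bird minimum.
Boundary conventions, where the prose of the protocol leaves them open,
are fixed as follows and tested:

* HDOP ≥ 10 removed; position error ≥ 30 m removed; **HDOP governs when
  both are present** (the error criterion is the fallback for devices that
  do not report HDOP); fixes reporting neither pass.
* AGL range −50…4000 m inclusive at both ends ("within the range" read
  inclusively; flagged as a convention, not a fact).
* Flight filter removes fixes with speed < 2 m s⁻¹ **and** AGL < 100 m;
  failing one criterion is not enough.
* Eight weeks = exactly 56 × 86 400 s; the fix exactly at the boundary is
  retained.
* Daylight = geometric solar altitude ≥ 0°, from the NOAA solar-position
  equations with refraction ignored (civil twilight vs geometric sunrise
  was not specified; geometric sunrise is assumed). Any algorithm accurate
  to minutes would do; the tests pin the implementation to an independent
  declination/equation-of-time oracle within ±10 minutes.
* Per-minute subsampling keeps the **earliest** fix in each calendar UTC
  minute (deterministic and order-stable; which fix to keep was
  unspecified). It runs after all removal filters — running it earlier
  could elect a fix that a later filter deletes, silently emptying that
  minute; a test demonstrates the order sensitivity.
* Birds with fewer than 100 surviving fixes are dropped.
* Raster cells are half-open `[x0, x0+res)` with rows counted top-down, so
  a point on a shared edge belongs to exactly one cell.

## Terrain derivations

Slope and aspect use Horn's 3×3 finite differences (the common GIS
default); aspect is encoded as eastness = sin(aspect) and northness =
cos(aspect) measured clockwise from north, with flat cells assigned
(0, 0). TPI is the centre-excluded mean difference over the 9-pixel
window (Wilson's definition), and slope unevenness is the same operator
applied to the slope band. The source protocol names its toolchain rather
than formulas, so these are documented conventions; tests verify them
against analytic planes and a brute-force per-cell oracle. Wind speed is
produced at 100 m resolution and resampled to the 25 m grid bilinearly
(a continuous field — no class-mixing concern), with edge cells clamped
to the outermost coarse-cell centres. Any cell with nodata in any band is
dropped from the feature table (no imputation), with a count kept.

## What the synthetic world emulates — and what it does not

The generator is the package's test bed and defines its study
conditions. Terrain is a Gaussian-smoothed random field (FFT-filtered
white noise; the contract is autocorrelation, reproducibility and
amplitude, not geomorphology). Land cover (10 classes) and geology (4)
are quantile-sliced smoothed fields; ibex and chamois occurrence are
logistic transforms of fields coupled to elevation, so food effects are
learnable; wind lives on a 4×-coarser grid to exercise resampling; the
geoid undulation is a smooth ±60 m field (realistic geoid scale without a
geoid model). All coordinates are planar metres; a fixed linear anchor
(46.5°N, 8°E) maps them to geographic coordinates for the daylight
machinery only.

The per-fix truth is a logistic model: P(AGL < 200) =
logistic(intercept + β·features), with the continuous features
standardized by their world-wide moments. The default β makes slope the
dominant driver (+1.5), with southern exposure (northness −0.6), wind
(+0.5), ibex (+0.5) and smaller terms — the qualitative pattern expected
for a soaring scavenger. Labels are drawn from the truth; true AGL is
then uniform on [0, 200) for class 1 and [200, 1500) for class 0 — a
modelling convenience that matches the binary response while exercising
both classes, **not** a claim about real flight-altitude distributions.
Reported altitudes add N(0, 5 m) vertical noise and, for
ellipsoid-reporting birds, the undulation. Contamination (night fixes at
local solar midnight, perched fixes, HDOP/error violations, early
post-release fixes, out-of-region fixes) is injected at configured rates
and flagged, so each cleaning stage's removals can be audited *exactly*.
`bayes_auc()` Monte-Carlo-estimates the discrimination ceiling of the
generating process; parameter-recovery tests require a trained model to
come within 0.05 of it.

What passing tests therefore show: the pipeline recovers a known
monotone generating process, its filters remove exactly what they claim,
and its maps are internally consistent. What they cannot show: behaviour
on real telemetry with home ranges, serially correlated movement,
device-specific error structure, or terrain-correlated GPS bias — none
of which the generator attempts.

## Evaluation design

Both cross-validation schemes use a **fixed 20-epoch** protocol with no
early stopping (stated for the bird CV; assumed for the block CV, which
needs no per-fold validation split then). Leave-one-bird-out trains one
model per bird; a held-out bird with single-class fixes gets an undefined
AUC, excluded from the mean with a warning. Spatial blocks are
axis-aligned squares tiling the region bounding box from its origin
(partial edge blocks kept as full blocks), dealt to five folds by a
seeded shuffle balanced to within one block.

The block-size recommendation fits an exponential variogram
γ(h) = c₀ + c₁(1 − e^(−h/a)) per continuous band by weighted least
squares on 15 log-spaced lag bins (bin counts as weights), profiling the
length scale over a log grid with the two amplitudes solved per
candidate under non-negativity. The practical range is 3a and the
recommendation is the median over bands (the aggregation of the original
tooling is unspecified). Two numerical guards matter: among candidate
scales within 1% of the best SSE the smallest is taken, and if the
structure expressed within the observed lag window is under 10% of the
sill the band is declared pure nugget and collapses to the cell scale —
otherwise sampling noise in a flat variogram can masquerade as
kilometre-scale structure. The reference study's 5719 m suggestion is a
property of its real layers, not a target for this implementation.

Permutation importance permutes each predictor group's rows jointly
(one-hot groups move intact), with the drop in AUC averaged over 10
seeded replicates. The headline form is the **relative** percentage drop
100·(AUC₀ − AUCₚ)/AUC₀, with the absolute percentage-point drop as an
option, since the reporting convention ("drop in training AUC (%)") is
ambiguous; both groupings — per-predictor, and the merged
aspect/food preset — are available. ICE curves sweep a focal variable
over an equally spaced grid on its natural scale (class set for
categorical variables), normalizing with the stored training statistics
before prediction; the PD curve is definitionally the column mean of the
ICE matrix, and a test checks the identity exactly.

## Mapping stage

Bagging draws bootstrap resamples (with replacement, same size) of the
70% training split, trains each member with early stopping against the
shared 30% validation split, projects every member over all valid cells
(cell features built exactly as `extract_features()` does), and
aggregates the cellwise mean with empirical 2.5/97.5 percentiles (linear
interpolation between order statistics — the default percentile
definition; with B = 30 the method matters, hence it is documented; the
interval form "95% credible interval" was unspecified, percentiles
assumed). Mean and percentiles may cross for small B; only lower ≤ upper
is guaranteed.

The binarization threshold is the **largest** threshold whose
true-positive rate on the selection data is ≥ 95%, found by scanning the
unique scores; binarization then uses ≥, so the achieved sensitivity
carries over exactly. Which split the threshold is computed on was
unspecified; the default is the full modelling dataset (train +
validation), with either split selectable — the sensitivity target is a
property one wants to hold on everything the model will be applied to,
and the full dataset is the least optimistic choice available without a
third split. The joint map is the cellwise product of occurrence and
low-flight probabilities; the high-risk map keeps the 4-level conflict
surface where low flight is predicted and zeroes it elsewhere, with area
shares computed as cell counts × cell area (partial cells ignored —
raster-native accounting).

## Problem sizes and determinism

The analysis drivers and the test suite run deliberately reduced
configurations chosen to estimate every quantity stably: worlds of
60–120 cells a side, 6–10 birds, 600–5000 fixes per bird (the
acceptance script generates ~50 000 raw fixes), grids of 4–8
configurations in the driver (the full 216 enumerate instantly; training
them all is a compute decision, not a code change), and bagging with
B = 10 in the driver versus 30 in the full protocol. Every stochastic
step — terrain noise, schedules, label draws, initialization, shuffling,
dropout, bootstraps, fold deals, permutations — flows from explicit
integer seeds, and generation is bit-reproducible for a given
configuration.

## Known limitations

* The synthetic world has no movement model: fixes are independent draws
  over cells, so spatial-block CV on it measures plumbing, not the
  spatial-transfer pessimism real trajectories would show.
* The real study's headline numbers (proportion below 200 m, AUCs around
  0.7, importance percentages, Swiss area shares) depend on proprietary
  tracking data and real geodata; nothing here reproduces or targets
  them.
* Occurrence and potential-conflict inputs are consumed, not modelled;
  the driver stands them in with synthetic surfaces.
* Rasters are read and written as ESRI ASCII grids — portable plain text
  any GIS ingests — rather than GeoTIFF, and no CRS transformations are
  performed (planar metres throughout).
* AUC on heavily tied score vectors uses midranks (ties count ½), which
  is also what the exhaustive-concordance oracle computes.
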