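---
title: "Methods: snowbed phenology from microclimate, BBCH observations and phenocams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snowbed phenology from microclimate, BBCH observations and phenocams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nivophen)
```

## The problem

Alpine snowbeds are topographic depressions where late-lying snow
compresses the growing season into a few weeks. As snowmelt advances
under climate warming, the question is how the specialist plant
community responds: do species track the melt date opportunistically, or
follow internal developmental programs? `nivophen` implements the full
analysis chain for a two-site ("early" vs "late" snowmelt)
space-for-time monitoring design: microclimate covariates from soil
temperature, ordinal BBCH phenophase processing, phenocam greenness
extraction, season phenometrics, penalized-spline phenology models with
cross-site prediction, and the phenological development rate (PDR)
statistic.

Because the package must be testable without field data, it ships a
synthetic scenario generator (`nivophen_scenario()`,
`simulate_scenario()`) whose defaults reproduce the structure of such a
design: two sites with contrasting melt dates, three years, 8 + 4
permanent plots with 16 subplots each (one reduced to 14), five species,
fortnightly observations, and an hourly phenocam.

## Microclimate model

Soil under an insulating snowpack sits near 0 °C; once snow is gone the
soil tracks the atmosphere. Three quantities derive from the hourly
record of each plot:

* **DOSM** (day of snowmelt): the first day whose daily mean soil
  temperature exceeds 2 °C and stays above it for a configurable number
  of consecutive days (`detect_snowmelt_day()`). The persistence default
  is one full day: the published rule is instantaneous, but a
  daily-mean basis with one-day persistence is robust to single hourly
  spikes under a thinning snowpack, which an instantaneous rule would
  misread. Whether the original analysis applied any persistence is not
  stated; the default is a documented choice, not a claim.
* **DFSM**: calendar days since DOSM.
* **GDD**: cumulative daily mean temperature above a 0 °C base from
  DOSM onward (`compute_gdd()`). The base of 0 °C retains the growth
  response of snowbed species at low temperature. GDD is accumulated on
  daily means (the standard agro-climatological convention), not on
  hourly sums divided by 24; an oracle test pins this convention.
  Days with fewer than 75% of their hourly records are interpolated
  linearly from neighbouring days and flagged.

The summary window for the mean snow-free soil temperature is the
period from DOSM to the end of the record (the snow-free period); the
averaging window of the published site summaries is not stated, and the
snow-free period is the default here.

## The BBCH phenophase scale

Observations use an ordinal scale adapted to snowbed communities, from
0 (plants not visible) to 59 (completely senescent), with six principal
growth stages and morphotype-specific descriptions for annuals (A),
perennials (P) and graminoids (G); code 47 ("late milk") exists only
for graminoids. The scale ships as a packaged CSV (`bbch_scale()`), and
`validate_observations()` enforces both membership and morphotype
compatibility.

Codes are stored as integers (09 = 9) and ordinal distance is plain
integer difference, because the downstream models treat the scale as
quasi-continuous. The plot-level response is the **median** subplot
code per species and date; with an even subplot count the median is the
mean of the two central codes and may fall between valid codes — it is
deliberately kept as a real number. Medians are computed over all
subplots, including zeros where the species is absent (whether the
original analysis excluded absent subplots is unstated; all-subplot
medians are the default and documented).

## Phenocam greenness

The green chromatic coordinate of an image is GCC = G / (R + G + B) of
the mean RGB over a region of interest. Grey soil gives exactly 1/3 and
the index is invariant to uniform brightness scaling; both identities
are tested. Quality control (`qc_filter()`) mirrors standard phenocam
practice:

* exposure time ≤ 50 s; exposure ratio ≥ 2 (the ratio is a
  camera-reported quantity and is treated as metadata pass-through — it
  cannot be reconstructed from pixels);
* acquisition between 10:00 and 17:00. The published wording couples
  the time window to "long exposure times"; the default here is a hard
  window, with a lenient mode that keeps outside-window frames when the
  exposure is short. Both are implemented because the wording is
  ambiguous;
* a brightness filter dropping images whose mean luminance falls
  outside a quantile band of the batch (default 2.5%–97.5%; the
  published thresholds are unstated, so this is a configurable default);
* a cluster filter: 2-means on (luminance, GCC), dropping the brighter,
  less green cluster (snow/fog frames) — but only when the clusters are
  separated in luminance by a margin (default 10% of the median), so
  that clean batches are not split arbitrarily. The published analysis
  names a clustering filter without defining it; this is the package's
  own concrete definition.

Each rule is evaluated as an independent per-record predicate, with the
brightness band and the clustering computed once on the whole input
batch. This makes retention monotone — relaxing any single rule can
only grow the retained set — which is tested as a property.

The retained per-image GCC series is smoothed to a daily series by a
moving-window percentile (`percentile_smooth()`): default the 90th
percentile over a trailing 4-day window, with the linear-interpolation
percentile definition pinned by a brute-force oracle test. With window
1 and percentile 100 the smoother degenerates to the daily maximum
series; both series are written by the pipeline.

## Season phenometrics

`extract_season_metrics()` partitions a daily GCC series into five
events. POS is the day of the seasonal maximum (earliest on ties; the
plateau extent is carried by SPS/EPS). SPS and EPS are the first and
last days with GCC within 95% of the maximum, read as
`gcc >= 0.95 * gcc_max` — the only reading that yields a contiguous
plateau period. SOS and EOS are not defined in the published analysis;
they are implemented as a threshold crossing at 10% of the seasonal
amplitude above the pre-season baseline (median GCC of the first five
snow-free days), a standard greenness-threshold phenometric consistent
with reported season starts shortly after snowmelt. The plateau is not
required to be contiguous; a fragmented plateau is flagged rather than
rejected. Event days are scale-invariant and shift-equivariant, and a
series truncated before browning yields a flagged partial result.

The pipeline reads events off the **daily-maximum** series rather than
the P90/4-day series. The trailing percentile window is causal: on the
decline it reports values from up to three days earlier, which lags
EPS/EOS by up to `window - 1` days by construction. The daily-maximum
series — the series on which the published season events are marked —
has no such lag, and the generator round trip recovers all five events
exactly at zero camera noise.

## Smooth models and cross-site prediction

Plot-level median phenophase is modelled as a smooth function of a
single climate predictor (GDD, DFSM or DOY) with plot and year random
intercepts (`fit_phenophase_smooth()`), using `mgcv`: a penalized cubic
regression spline (basis dimension 8 by default — with 10–15
observation dates per season, little more flexibility is identifiable),
random effects as penalized group intercepts (`bs = "re"`, exactly the
ridge-equivalent formulation), Gaussian response on the
quasi-continuous scale, and all smoothing/variance parameters selected
jointly by REML. The published analysis does not state its smoothing
selection or basis dimension; these are documented defaults. Reported
AIC is conditional on effective degrees of freedom, the additive-model
convention; absolute AIC values are convention-dependent and are not
compared against published magnitudes.

The three candidate predictors are screened for collinearity
(`screen_predictors()`; they are typically correlated above 0.9, which
is why models are single-predictor), compared by AIC
(`compare_predictors()`; ties break by the mechanistic priority
GDD > DFSM > DOY), and the winning GDD model fitted at the late site
predicts the early site (`predict_cross_site()`) with random effects
excluded — a pooled population-level curve, since whether the original
predictions were per plot is unstated. Predictions are clamped to
[0, 59] with pre-clamp values retained, and target GDD beyond the
training range is flagged as extrapolation.

Ecosystem greenness is related to species development by an additive
model of GCC on per-species phenophase smooths
(`fit_gcc_species_model()`, k = 4 per smooth). Monotone phase
trajectories of co-occurring species are mutually concurve, so exact
significance attribution has limits: the test suite requires the
driving species to rank first in evidence nearly always, rather than
demanding a clean significant/non-significant split in every replicate.

## The phenological development rate

PDR is the slope of median phenophase against accumulated GDD over the
development window: from the first observation at code ≥ 09 (emergence)
to the last observation at code < 59 (before cycle completion),
endpoints inclusive (`compute_pdr()`). Two readings of "slope of the
regression line between the first and final observation" are offered:
ordinary least squares over all in-window observations (default — a
regression line over an interval implies a fit, not a chord) and the
two-point chord, which agrees with OLS on two-point windows. The
regression axis is GDD, not calendar days: realistic rates of
0.06–0.095 BBCH units are consistent with ~50 BBCH units over 600–800
degree-days; a per-day axis is available via `axis = "day"`.

Estimates aggregate to species/site means and SDs over plot-year units
(`aggregate_pdr()`), and sites are compared by Welch's two-sample
t-test on plot-year values (`compare_pdr_sites()`) — appropriate for
the unequal plot numbers (8 vs 4) and variances of the design. The
published table does not name its test, and recomputing from its
printed summaries under Welch's t does not reproduce every printed
p-value, suggesting a different unit of replication; a year-paired test
is therefore offered as an alternative rather than guessing.

## The synthetic generator and what it does (not) show

The generator's defaults are the study conditions: melt days 194/182/191
(late) and 164/193/175 (early), summer mean soil temperatures 9.8 and
10.4 °C, a 4 °C diurnal amplitude, day-to-day weather noise of 2 °C,
fortnightly observations, subplot noise of 1.5 BBCH units (within-plot
heterogeneity is not published; this is a free scenario parameter), and
five species programs with onset lags of 0–250 degree-days and rates of
0.060–0.089 BBCH per degree-day reproducing the observed ordering
(earliest transitions for *Salix herbacea*, a 250-GDD delay for the
annual *Euphrasia minima*).

Numerical choices worth knowing:

* Pre-melt soil temperature is uniform in [−0.5, 1.5] °C — snow
  insulation keeps it strictly below the 2 °C threshold, so melt
  detection round-trips exactly. Post-melt daily means are floored at
  2.5 °C so a cold snap cannot move the first crossing off the
  constructed melt day.
* Species phase is a linear ramp in GDD after the onset lag, snapped to
  the nearest valid morphotype code (ties to the lower code). This is
  the simplest monotone program consistent with a rate-based
  description and makes PDR recovery analytic — almost. Snapping to the
  sparse ordinal code set creates shelves at the 0→9 and 55→59 gaps, so
  individual noise-free plot slopes carry a few percent of bias (up to
  ~5% at the fortnightly cadence) even though the mean across plots
  recovers the generating rate to well under 2%. Recovery tolerances in
  the tests are set accordingly (±10% per aggregated species/site at
  the design's noise level, matching what the estimator can claim).
* The seasonal GCC curve is piecewise **linear** through anchor points
  that encode the five events exactly (with a 10⁻⁶ offset at the
  threshold anchors to be robust to floating-point comparison), rather
  than a smooth double-logistic. A logistic family cannot guarantee
  ±1-day event round trips at daily sampling without tuning steepness
  per scenario; the anchored piecewise curve makes the round trip exact
  by construction while keeping the rise–plateau–decline shape.
* Camera artifacts are injected with ground-truth labels: over-exposed
  frames (exposure > 50 s, brightened), fog frames (bright and grey,
  GCC ≈ 1/3) and out-of-window timestamps, at default rates of 2–3%.
* Determinism: every simulation call takes an explicit seed, and the
  scenario driver derives per-plot substream seeds arithmetically, so a
  fixed scenario seed yields byte-identical outputs.

The generator emulates the *statistical structure* the analysis
assumes — monotone thermal-time development, a rise–plateau–decline
greenness season, snow-insulated temperature plateaus — not real data.
Passing round trips show the estimators are correct and the pipeline
coherent; they do not show that real snowbed phenology is linear in
GDD, that real within-plot noise is Gaussian, or that real camera
artifacts are as separable as the injected ones. Spatial autocorrelation
between subplots, nonlinear temperature–growth response and radiative
camera effects are deliberately out of scope.

## Problem sizes used in tests

The recovery suite runs the full two-site design (12 plots × 3 years ×
5 species × 16 subplots, hourly temperatures over days 120–280) for 20
scenario seeds, and the acceptance script for 10; the power simulation
of the site comparison uses 500 replicates at the observed effect size
(means 0.060 vs 0.072, SDs 0.006/0.005, n 24/12). These sizes were
chosen to estimate rates with enough replicates while keeping a full
run at desk scale.

## A worked example

```{r example, eval = FALSE}
scn <- nivophen_scenario(seed = 42)
run <- run_pipeline(pipeline_config(output_dir = "run1", seed = 42,
                                    scenario = scn))
run$results$pdr$comparison
```

## Known limitations

* The smooth models are Gaussian; no ordinal link is offered (the
  quasi-continuous treatment follows the source analysis).
* Season metrics need a series spanning rise and fall; monotone series
  yield flagged partial results rather than estimates.
* The exposure-ratio rule can only be applied when the camera reports
  the ratio.
* Published model-fit magnitudes (R², AIC, prediction errors) from the
  field data are reproduced structurally (same tables, same columns) on
  synthetic data, not numerically — that would require the archived
  field dataset.
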