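# nivophen

Snowbed phenology from microclimate, BBCH field observations and
phenocam imagery.

Alpine snowbeds — depressions where late-lying snow compresses the
growing season — are among the habitats most exposed to advancing
snowmelt. A standard way to study their future is a space-for-time
design: monitor an early-snowmelt and a late-snowmelt site in parallel,
relate each species' development to microclimate, and ask whether models
trained under today's conditions (late site) predict phenology under
tomorrow's (early site).

`nivophen` implements that analysis chain end to end:

* **Microclimate** — day of snowmelt (DOSM) from hourly soil
  temperature (first daily mean > 2 °C, with configurable persistence),
  days from snowmelt (DFSM), and growing degree days
  (GDD = Σ max(T̄_day − T_base, 0), base 0 °C).
* **Phenophases** — the snowbed-adapted ordinal BBCH scale (codes
  0–59, morphotype variants for annuals/perennials/graminoids),
  validation, subplot-to-plot **median phenophase**, and alignment with
  DOY/DFSM/GDD.
* **Phenocam** — green chromatic coordinate GCC = G/(R+G+B) over an
  ROI, quality control (exposure, exposure ratio, 10:00–17:00 window,
  brightness and snow/fog cluster filters), and 90th-percentile
  smoothing over a 4-day moving window.
* **Phenometrics** — the five season events SOS, SPS, POS, EPS, EOS;
  SPS–EPS delimit the period with GCC within 95% of the seasonal
  maximum.
* **Models** — penalized regression spline models of median phenophase
  vs GDD/DFSM/DOY with plot and year random intercepts (via `mgcv`),
  predictor selection by AIC, a GCC-by-species additive model, and
  cross-site prediction with error assessment.
* **PDR** — the phenological development rate: the OLS slope of median
  phenophase against GDD between the first observation at code ≥ 09 and
  the last at code < 59, aggregated over plot-years and compared
  between sites with Welch's t-test.
* **Synthetic data** — a deterministic scenario generator (two sites ×
  3 years × 8+4 plots × 16 subplots, five species on thermal-ramp
  programs, an hourly phenocam with labelled artifacts) so that every
  estimator can be validated by round trip without field data.

## A worked example

```r
library(nivophen)

scn <- nivophen_scenario(seed = 42)   # the default two-site design
run <- run_pipeline(pipeline_config(output_dir = "run1", seed = 42,
                                    scenario = scn))

run$results$pdr$comparison
#> # A tibble: 5 × 9
#>   species            m_early sd_early n_early m_late sd_late n_late     p stars
#> 1 Euphrasia minima    0.0704 0.00236       12 0.0706 0.00290     24 0.852 ""
#> 2 Gnaphalium supinum  0.0580 0.000893      12 0.0576 0.00125     24 0.274 ""
#> 3 Poa alpina          0.0780 0.000988      12 0.0776 0.00180     24 0.341 ""
#> 4 Salix herbacea      0.0897 0.00278       12 0.0903 0.00221     24 0.499 ""
#> 5 Veronica alpina     0.0674 0.00161       12 0.0676 0.00139     24 0.752 ""
```

Each row is one species: the mean (M) and SD of the development rate
(BBCH units per degree-day) over plot-year estimates at each site, and
the two-sided Welch p-value for a site difference. Here both sites were
generated from identical species programs, so rates agree and no
contrast is significant — the generating truth (0.089 for *S. herbacea*
down to 0.060 for *G. supinum*) is recovered within a few percent.

Predictor selection for one species shows why thermal time wins over
calendar time when melt dates differ between years:

```r
run$results$models$comparison |> dplyr::filter(species == "Salix herbacea")
#>   predictor    r2   aic   edf species        site  winner
#> 1 gdd       0.999  308.  6.94 Salix herbacea late  TRUE
#> 2 dfsm      0.998  507.  6.82 Salix herbacea late  FALSE
#> 3 doy       0.988  796.  5.89 Salix herbacea late  FALSE
```

And the phenocam season metrics per site-year (events in day of year,
read off the daily-maximum GCC series):

```r
run$results$metrics[, c("site", "year", "sos", "pos", "eos", "gcc_max")]
#>   site   year   sos   pos   eos gcc_max
#> 1 late   2018   196   215   270   0.470
#> 2 late   2019   185   202   267   0.466
#> 3 late   2020   193   210   267   0.469
#> 4 early  2018   167   187   266   0.447
#> 5 early  2019   196   219   266   0.452
#> 6 early  2020   175   198   271   0.450
```

The early site greens up earlier in most years (its 2019 season was
late by construction — a delayed-melt year), and the late site peaks
higher, matching the scenario's site contrast.

All stage outputs (`snow_seasons.csv`, `climate_alignment.csv`,
`plot_phenophases.csv`, `gcc_daily.csv`, `season_metrics.csv`,
`model_comparison.csv`, `predictions.csv`, `pdr_estimates.csv`,
`pdr_comparison.csv`) plus a `manifest.json` land in the output
directory, byte-identical across reruns with the same seed.

## See also

The methods vignette
(`vignettes/snowbed-phenology-methods.Rmd`) documents the models and
their assumptions, every tunable parameter with its default and
rationale, the design decisions taken where the published methods are
silent, and what the synthetic round trips do and do not demonstrate.
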