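Package: nivophen
Title: Snowbed Phenology from Microclimate, Field Observations and Phenocams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for alpine snowbed phenology under
    contrasting snowmelt regimes. Derives day of snowmelt, days from
    snowmelt and growing degree days from hourly soil-temperature logs;
    validates and aggregates ordinal BBCH phenophase observations to
    plot-level medians; extracts quality-controlled green chromatic
    coordinate (GCC) series from time-lapse phenocam imagery; partitions
    the greenness season into start, peak and end events; fits penalized
    regression spline models of phenophase against climate covariates
    with plot and year random effects; predicts phenology across sites;
    and computes the phenological development rate (PDR), the slope of
    phenophase against thermal time. Ships a synthetic scenario
    generator with the statistical structure of a two-site, multi-year
    snowbed monitoring design so every stage can be tested without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mgcv,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
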