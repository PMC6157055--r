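Package: bpimpact
Title: Budget Impact Modelling of Hypertension Guideline Adoption
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic two-scenario cohort model and second-order Monte
    Carlo probabilistic sensitivity analysis for the budget impact of moving
    hypertension diagnosis and treatment from the 140/90 mmHg cut-off to the
    2017 AHA/ACC 130/80 mmHg cut-off in a national healthcare system over a
    three-year horizon. Includes a parameter file format with Beta, Poisson
    and Gamma sensitivity distributions, synthetic generators for population
    projections, age-specific prevalence tables and administrative event
    series, expected cardiovascular event and cost accounting, exponential
    smoothing validation forecasts, and tabular reporting of results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
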