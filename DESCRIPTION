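Package: ssbtax
Title: Micro-Simulation of Sugar-Sweetened Beverage Taxation Effects on
    Energy Intake, Body Weight and Obesity Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ex-ante fiscal-policy simulation pipeline for
    sugar-sweetened beverage (SSB) taxation in an adult population.
    Translates a tax scenario (rate, pass-through, taxed beverage
    categories) into per-category price changes, applies own- and
    cross-price demand elasticities to individual-level beverage
    consumption, converts the resulting daily energy-intake change into
    body-weight and BMI change with a simplified steady-state
    energy-balance rule, and reports survey-weighted overweight and
    obesity prevalence changes with bootstrap confidence intervals by
    sex and age stratum. Includes a seeded synthetic-population
    generator calibrated to published Brazilian adult beverage-intake
    and anthropometry baselines, and a sensitivity analysis over tax
    pass-through rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
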