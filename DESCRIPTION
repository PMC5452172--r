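Package: dietscen
Title: Dietary Scenario Simulation Modelling for Discretionary Food and
    Beverage Intake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic dietary simulation pipeline for population
    nutrition surveys. Combines person-level 24-hour recall intake records
    with a per-100 g food composition table to compute population-weighted
    mean daily nutrient profiles, then models the nutritional impact of
    moderation (reduced discretionary intake with optional energy
    compensation), substitution (replacement of discretionary choices with
    core foods and beverages via replacement ratios) and reformulation
    (altered saturated fat, added sugar, sodium and alcohol content)
    scenarios, with sensitivity bounds. Includes a calibrated synthetic
    population generator so the full pipeline is testable without
    access-restricted survey microdata, an aggregate mode operating directly
    on published class-level mean-intake tables, tidy result accessors and
    ggplot2 visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
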