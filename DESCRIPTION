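Package: ppmr
Title: Predator-Prey Mass Ratios Across Temperature and Fishing Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing predator-prey mass ratios (PPMR) from fish
    stomach-content records across spatial gradients of sea-surface
    temperature and commercial fishing effort. Computes biomass-weighted
    PPMR per predator stomach, assigns ICES statistical rectangles, joins
    gridded monthly temperature (with a one-month lag) and annual fishing
    effort, fits linear mixed-effects models with temperature-by-effort
    interactions, classifies species-level body-size responses, and
    ordinates family-level prey communities with non-metric
    multidimensional scaling. Includes a synthetic-data generator with
    known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    lme4,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
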