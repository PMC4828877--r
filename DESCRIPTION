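Package: gpworkforce
Title: Needs-Based General Practitioner Workforce Planning Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-part simulation model for regional general practitioner
    (GP) workforce planning. A deterministic state-transition cohort model
    projects the GP stock by sex, age band, location and work status,
    with entries (graduates, in-migration), temporary and permanent exits,
    aging between bands and time-varying transition probabilities; an
    accept-reject calibration retains all sampled parameter sets whose
    projections deviate less than a set tolerance from smoothed observed
    stocks. A need sub-model fits base-year consultations-per-case service
    norms from attendance, condition-management and burden-of-disease data,
    projects required consultations under alternative need and utilisation
    scenarios, and converts them to required full-time-equivalent GPs.
    Includes seeded synthetic-data generators for every input table,
    schema-validated CSV readers and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
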