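Package: reefstatus
Title: Coral-Reef Recovery Status from Monitoring Data: Metrics, Stressor
    Indices and Predictive Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline linking coral-reef recovery status to
    water quality and herbivory. Computes ecological status metrics
    (percent cover from point-intercept video transects, benthic substrate
    ratio, coral species richness per quadrat, Margalef's d, herbivorous
    fish biomass from stationary point counts, macroinvertebrate density)
    from raw monitoring records; builds a rank-based water-quality index
    and a replicate-crossed water-quality-by-herbivory interaction term;
    classifies sites into high and low recovery categories; fits
    power-transformed multiple regressions selected by AIC; and
    interpolates predicted status over the stressor plane. A seeded
    synthetic-data generator emulates a high-island monitoring program
    (17 sites, video belt transects, point quadrats, stationary point
    counts, a cyclone disturbance pulse) so the whole pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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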