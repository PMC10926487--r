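Package: alpinemoth
Title: Camera-Trap Monitoring and Flight Behaviour Analysis of Alpine
    Aestivating Moths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing wildlife-camera records of flying insects
    at alpine aestivation sites, developed around the Bogong moth (Agrotis
    infusa) monitoring problem. Provides quality filtering of automated
    detections, solar twilight geometry and evening counting windows,
    weather covariate assembly with adiabatic lapse-rate temperature
    projection, greedy collinearity pruning, Poisson regression of evening
    counts with image-count exposure, a cumulative-maximum arrival and
    departure phenology model with median occupancy dates, and a circular
    statistics pipeline for flight-track orientation (Moore's modified
    Rayleigh test, Mardia-Watson-Wheeler tests, and von Mises orientation
    model selection by AIC). A seeded synthetic-data generator emulates the
    statistical structure of the field data so every analysis stage can be
    tested without camera imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
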