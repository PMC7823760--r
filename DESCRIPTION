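Package: fwaging
Title: Healthy-Aging Scoring, Factor Screening and the F-W Regional Index
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for operational healthy-aging (HA) analysis of elderly
    survey cohorts: scoring of the four HA criteria (physical health,
    activities of daily living, mental health, social participation) on
    individual records with Cronbach's alpha scale reliability, Pearson
    chi-square factor screening and block logistic regression, backward
    stepwise logistic regression with a full elimination trace, and the F-W
    composite regional index HA = sum(Fi * Wi) built from micro-model
    log-odds-ratio weights and regional factor ratios, with trend
    classification and economic-zone aggregation. Includes a synthetic-data
    module that emulates CHARLS-style micro records and provincial yearbook
    panels with known ground truth, and a reproducible pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
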