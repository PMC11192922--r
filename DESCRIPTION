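Package: forestsec
Title: Forest Ecological Security Indexing, Hotspot Detection and
    Geographically Weighted Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating regional forest ecological security from a
    pressure-state-response (PSR) indicator panel and for analysing its
    spatial structure and drivers. Computes an entropy-weighted composite
    forest ecological security index (ESI) from min-max standardized
    indicators, classifies spatial units into cold/hot-spot levels using the
    local Getis-Ord Gi* statistic with Jenks natural-breaks classes, and fits
    geographically weighted regressions (GWR) of the index on socioeconomic
    drivers with a fixed Gaussian kernel and leave-one-out cross-validated
    bandwidth. Includes a synthetic-data generator with known coefficient
    surfaces so every stage is testable without external data, plus packaged
    transcriptions of published provincial GWR coefficient tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
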