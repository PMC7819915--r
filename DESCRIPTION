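Package: tnz
Title: Flow-Through Respirometry Calorimetry and Thermoneutral-Zone Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the computational chain of flow-through respirometry
    studies of avian thermoregulation: steady-state gas-exchange calorimetry
    (oxygen consumption, carbon dioxide production and evaporative water loss
    from excurrent gas fractions), demultiplexing and baseline correction of
    multichannel analyzer traces, extraction of steady-state windows,
    continuous segmented (piecewise-linear) regression of metabolic rate,
    body temperature and evaporative heat loss against ambient temperature
    with cluster-bootstrap breakpoint standard errors, partitioning of
    evaporative heat loss into respiratory and cutaneous avenues from
    two-line mask respirometry, ANOVA-based intraclass-correlation
    repeatability with covariate adjustment, and a synthetic-data generator
    with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
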