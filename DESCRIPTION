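Package: harvshap
Title: Harvest-Readiness Classification of Plant Image Time Series with
    Grouped Shapley Acquisition-Day Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding when field-grown plants such as cauliflower
    are ready for harvest from image time series. The package builds
    harvest-day-anchored image time series from per-plant observation
    manifests, trains a compact time-series classifier in which every image
    is mapped by a shared encoder to a 32-dimensional embedding augmented
    with a sinusoidal positional encoding of plant age, attributes
    predictions to individual acquisition days with grouped Shapley values
    (exact enumeration and a kernel-weighted sampled estimator with
    training-set imputation), and iteratively excludes the acquisition day
    with the lowest mean absolute contribution to find smaller acquisition
    schedules that keep or improve accuracy. A synthetic field generator
    with known ground truth makes the whole pipeline testable without
    external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
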