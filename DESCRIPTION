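Package: mcdmeg
Title: Multisensory Correlation Detector Modelling of Audiovisual
    Behavior and Evoked Neural Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and fitting tools for the multisensory correlation
    detector (MCD), a Hassenstein-Reichardt-style circuit that computes the
    temporal correlation and lag between auditory and visual impulse
    trains.  The package designs click/flash sequences with decorrelated
    model outputs, jointly fits the detector time constants and per-task
    logistic links to causality and temporal-order judgments by marginal
    maximum likelihood, runs Monte-Carlo observational power analyses,
    processes multichannel epoched recordings (artifact rejection, sensor
    merging, unisensory-response removal, cluster-based permutation
    statistics), and encodes sensor time series with model-based temporal
    response functions estimated by cross-validated ridge regression.
    Every stage can be exercised end to end on synthetic data with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    igraph,
    jsonlite,
    pracma,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
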