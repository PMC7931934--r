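Package: plantmapr
Title: Annual Plantation Mapping from Multi-Temporal Reflectance with
    Pairwise Ensembles and HMM Smoothing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps tree plantations yearly from multi-temporal satellite
    surface-reflectance time series (46 eight-day composites x 7 bands per
    pixel-year, MOD09A1-style). Implements a one-vs-one pairwise ensemble
    classifier over aggregations of a 19-class land-cover taxonomy with
    Unknown-tie vote semantics, subclass-balanced training-set construction
    for imbalanced land-cover classes, hidden Markov model post-processing
    of each pixel's yearly label sequence with near-forbidden
    plantation-to-forest reversion, and an evaluation protocol against
    asymmetric noisy reference products (a high-recall/low-precision
    single-epoch plantation mask and high-precision/low-recall anchor-year
    land-cover maps). Ships a synthetic scene simulator so the full
    pipeline is testable without external satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
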