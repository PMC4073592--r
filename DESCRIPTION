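Package: xrqa
Title: Cross-Recurrence Quantification Analysis of Categorical and
    Continuous Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-recurrence quantification analysis (CRQA) of
    pairs of categorical or continuous time series. Builds cross-recurrence
    plots by time-delay embedding and radius thresholding, extracts the
    classical line-based recurrence measures (recurrence rate, determinism,
    mean and maximal diagonal line length, diagonal length entropy,
    laminarity, trapping time), computes diagonal-wise and windowed
    recurrence profiles for leader-follower lag analysis, performs
    contingency-table recurrence with per-state phi coefficients for
    categorical sequences, selects embedding parameters by average mutual
    information, false nearest neighbours and a targeted recurrence-rate
    radius search, and simulates coupled binary event series for method
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'coding.R'
    'embedding.R'
    'measures.R'
    'profiles.R'
    'contingency.R'
    'optimize.R'
    'simulate.R'
    'io.R'
    'run.R'
    'xrqa-package.R'
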