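Package: gcnet
Title: Spectral Granger-Causality Brain Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates frequency-domain (Geweke) Granger causality between
    regional brain time series from bivariate autoregressive models, averages
    the spectral estimates into canonical EEG bands, sparsifies the resulting
    weighted directed networks by group-contrast permutation t-tests, and
    summarises them with weighted-directed graph efficiency, degree
    centralities and directional fronto-posterior connectivity indices.
    Includes a stationary vector-autoregressive cohort simulator with
    band-specific directed coupling and an analytic spectral Granger-causality
    oracle, so the whole pipeline is testable without real EEG recordings.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    lme4,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
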