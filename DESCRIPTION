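Package: coreshift
Title: Critical-Transition Analysis of Sediment-Core Microbial Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising critical transitions in dated
    microbial community time series from sediment cores. Provides readers and
    writers for taxon-by-sample count tables with calibrated chronologies,
    rarefaction and taxonomic collapsing, alpha diversity with between-state
    tests, Bray-Curtis ordination (NMDS, ANOSIM, PERMANOVA) with
    stratigraphically constrained zonation and kernel-density bimodality,
    structural-change breakpoint detection, sliding-window early-warning signals
    (variance and lag-1 autocorrelation) and ARIMA forecast-deviation tests, and
    the core model: stage-wise generalized Lotka-Volterra inference by
    Tikhonov-regularized regression with k-fold cross-validation, local
    stability analysis from the Jacobian spectrum, and classification of
    pairwise interactions into mutualism, antagonism and exploitation. A
    synthetic-data module generates ground-truth two-regime scenarios so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
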