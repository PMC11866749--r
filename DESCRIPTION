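Package: mbcmsm
Title: Merging-Bias-Corrected Markov State Models from Weighted-Ensemble Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Runs weighted-ensemble (WE) simulations of discrete-state
    Markov chains with the REVO (Resampling Ensembles by Variation
    Optimization) resampler, records the full branched trajectory tree
    (cloning and merging events with walker weights), and estimates Markov
    state models from the tree. Lag times longer than one resampling
    interval systematically undercount transitions whose lineages were
    terminated by merging inside the lag window; the package implements the
    merging-bias correction that completes those lineages with powers of
    the one-step transition matrix, alongside the uncorrected estimator.
    Includes the 1D biased random walk benchmark with its analytic steady
    state, steady-state flux and mean first passage time calculators, and
    conformation-space-network export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'brw.R'
    'revo.R'
    'we-engine.R'
    'lagged-counts.R'
    'msm.R'
    'experiments.R'
    'io.R'
    'fixtures.R'
    'mbcmsm-package.R'
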