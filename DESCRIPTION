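Package: silacswap
Title: Design-Aware Analysis of Triplex SILAC Label-Swap Proteomics
Version: 1.0.0
Authors@R:
    person("EMF", "Proteomics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for semi-quantitative proteomics experiments that use
    triple-state (triplex) SILAC labeling with two reciprocal label swaps.
    Provides readers for MaxQuant-style protein-group tables, design-aware
    quality and composite Boolean filters, swap-bias diagnostics based on
    reciprocal-ratio correlation, an ensemble of differential-regulation
    detectors (fold change, intensity-binned significance B, Z-score, robust
    M-score, rank product, fold-change rank ordering statistic, and a
    moderated fold-change-threshold test with empirical-Bayes variance
    shrinkage), protein-set comparisons, Bayesian model-based term-set
    analysis with both exact enumeration and MCMC estimation, and a
    ground-truth synthetic data generator emulating the measurement
    structure of a double-label-swap SILAC study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
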