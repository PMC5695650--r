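Package: spafnirs
Title: Systemic-Physiology-Augmented fNIRS Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of systemic-physiology-augmented
    functional near-infrared spectroscopy (SPA-fNIRS) experiments with
    intermittent visual stimulation. Provides a ground-truth-annotated
    generator for multimodal physiological recordings (cerebral hemoglobin
    and oxygenation channels, capnogram, beat-derived cardiovascular
    channels, heart-rate-variability band powers, skin conductance), a
    preprocessing chain (movement-artifact reduction by moving-SD detection
    and spline subtraction, anti-aliased resampling, moving-average and
    robust local-regression smoothing, capnogram envelope end-tidal CO2 and
    respiratory-rate extraction, pulse-respiration quotient and
    cardiac-output proxy), stimulus-locked block averaging with
    subject-level signed-rank gating and group-level quantile regression
    with bootstrap confidence intervals, and significance-masked Spearman
    functional-connectivity networks with weighted graph metrics
    (assortativity, transitivity, density, global efficiency).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    signal,
    igraph,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'stats-tests.R'
    'block.R'
    'connectivity.R'
    'io.R'
    'methods-accessors.R'
    'preprocess.R'
    'simulate.R'
    'pipeline.R'
    'spafnirs-package.R'
LinkingTo: Rcpp
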