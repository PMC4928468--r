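Package: sipscfit
Title: Kinetic-Model Fitting of Individual Spontaneous Inhibitory
    Postsynaptic Currents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits individual (non-averaged) spontaneous inhibitory
    postsynaptic current (sIPSC) events recorded under voltage clamp with a
    user-configurable kinetic model.  Ships a gephyrin-dependent
    transsynaptic signaling model with a closed-form current solution, a
    built-in bi-exponential alternative, event detection and preprocessing
    (baseline removal, 20%-of-peak clipping, short/overlap rejection), a
    plain-text configuration dialect for fitted parameters with bounds,
    dependency and exclusion rules, multi-start derivative-free
    (principal-axis) optimization with RMSE acceptance thresholding,
    synthetic sIPSC data generation with pseudo-Voigt peak-amplitude
    distributions, and multilevel parameter-ensemble statistics (Spearman
    correlation structure, Kruskal-Wallis with Dunn or Tukey post hoc
    comparisons at experiment, cell and trace level).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    optparse,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
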