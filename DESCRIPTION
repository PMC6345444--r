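Package: sccnet
Title: Structurally Constrained Metabolite Concentrations in Mass-Action
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects metabolites whose steady-state concentration in a
    mass-action metabolic network is fixed by the network structure, a few
    rate-constant ratios, and a single flux ratio (structurally constrained
    concentrations, SCC). Provides flux-coupling analysis (blocked reactions,
    fully coupled reaction classes from linear-fractional programming and
    shared mass-action substrate columns), certificate-based detection of SCC
    metabolites, concentration-range computation over flux sets, estimation of
    relevant flux-ratio ranges by constraint-based optimization with a
    Charnes-Cooper transformed program, calibration of the structural
    constants from reference concentration measurements, knockout response
    prediction by minimization of metabolic adjustment, and a mass-action
    kinetics simulator with a planted-motif synthetic network generator that
    serves as the validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: GLPK
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quadprog,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
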