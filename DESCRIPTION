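Package: TrichoFBA
Title: Constraint-Based Modeling of Cell-Type Division of Labor in
    Trichodesmium erythraeum
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for constraint-based analysis of the two-cell-type
    division of labor in the marine diazotrophic cyanobacterium
    Trichodesmium erythraeum. Provides an S4 representation of
    genome-scale metabolic models with structural validation (element and
    charge balancing, dead-end detection, futile-cycle screening), a
    biomass-equation builder from measured macromolecular composition, the
    diazotroph and photoautotroph constraint sets, flux balance and flux
    variability analysis with maintenance-energy calibration and gene or
    reaction essentiality on a self-contained bounded-variable simplex
    solver, and a two-phenotype population dynamic FBA in which cells
    differentiate between nitrogen-fixing and carbon-fixing states in
    proportion to metabolite shortage. A reduced, fully balanced synthetic
    two-cell-type network with a brute-force equilibrium oracle supports
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    xml2,
    jsonlite,
    yaml,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
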