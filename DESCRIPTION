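Package: mcaBounds
Title: Inferring Required Activity Changes in Metabolic Adaptations by
    Metabolic Control Analysis and Linear-Programming Bound Contraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies transporter and enzyme activities whose decrease or
    increase is required to sustain a measured metabolic adaptation.
    Ensembles of scaled control-coefficient matrices are generated by
    constrained random sampling of metabolite elasticities (saturation
    bounds, thermodynamic disequilibrium, competitive substrate/product
    pairs, allosteric modifiers, moiety conservation), and a linear
    programming sweep contracts the log2 fold-change domains of all
    concentrations, fluxes and individual activities to their tightest
    intervals consistent with the control-coefficient equalities and the
    measurements. Final domains that contain only negative or only positive
    values mark molecular drivers of the adaptation. Includes small kinetic
    fixture models (with explicit rate laws and steady-state solving) for
    ground-truth validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    deSolve,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
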