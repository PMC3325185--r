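Package: invadosim
Title: Kinetic Modelling of MT1-MMP Turnover and ECM Degradation at Invadopodia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the turnover of the membrane-anchored protease
    MT1-MMP at invadopodia and to simulate its consequences for extracellular
    matrix (ECM) degradation. The package decomposes fluorescence recovery
    after photobleaching (FRAP) time courses into exponential mixtures,
    reconstructs recovery curves with a two-pool surface-turnover model,
    enumerates the combinatorial MT1-MMP/TIMP-2/proMMP-2 reaction network by
    rules, integrates the resulting mass-action system (well-mixed and as a
    3D reaction-diffusion model) with a fixed-step fourth-order Runge-Kutta
    scheme, and screens in-silico interventions (turnover and concentration
    reduction factors) through half-degradation times and degradation
    efficacies, including a synergy index against a multiplicative null.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    xml2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
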