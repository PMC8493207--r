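Package: ppcm
Title: Phylogenetic Comparative Models for Captive-Welfare Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for species-level comparative analyses of welfare
    indicators in captive populations: phylogenetic generalized least
    squares with maximum-likelihood estimation of Pagel's lambda,
    penalized phylogenetic logistic regression for binomial prevalence
    data, majority-rule consensus trees with averaged branch lengths,
    propagation of phylogenetic uncertainty over tree blocks with
    percentile confidence intervals, leave-one-out influence
    diagnostics, confound and collinearity screening, and a synthetic
    comparative-data generator with known ground truth for validating
    every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phangorn,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
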