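Package: habshape
Title: Phylogenetic Comparative Analysis of Microhabitat Evolution and
    Morphological Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how discrete microhabitat use evolves on a
    time-calibrated phylogeny and how it shapes morphological diversification,
    built around the salamander arboreality study design. Fits Mk models of
    discrete character evolution (ER/SYM/ARD) by maximum likelihood with AIC
    model selection, estimates marginal ancestral states, and samples Bayesian
    stochastic character maps by endpoint-conditioned uniformization to count
    microhabitat transitions and independent origins of a focal state.
    Processes raw morphology into species-level trait matrices: regression
    imputation of linear measurements, log Mosimann shape ratios, thin-plate
    spline completion of missing landmarks, and generalized Procrustes
    analysis with bending-energy sliding of semilandmarks. Provides
    group-structured comparative statistics (phylogenetic ANOVA with residual
    randomization, multivariate evolutionary-rate comparison, Stayton's C1 and
    C5 convergence measures, and an allometric-convergence permutation test),
    a synthetic-data generator for every input, and an end-to-end pipeline
    with classification-scheme and posterior-tree sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
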