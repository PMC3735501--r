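Package: oligopbmc
Title: Bayesian Hierarchical Analysis of Oligosaccharide Immunomodulation
    in LPS-Challenged Equine PBMCs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis workflow for in vitro immunomodulation experiments in
    which equine peripheral blood mononuclear cells are incubated with
    galacto-, fructo- and pectin-derived acidic oligosaccharide fractions
    (GOS, GOS/FOS, GOS/FOS/AOS) and challenged with lipopolysaccharide, and
    TNF-alpha, IL-10 and cell viability are read out by plate assays.
    Implements the incubation-mixture and endotoxin arithmetic for the
    carbohydrate formulations, a plate-level data model with left-censoring
    at the ELISA detection limits, a synthetic-data generator with per-horse
    random effects, a Bayesian hierarchical linear regression on
    log-transformed responses (random intercept and LPS/GOS/FOS/AOS random
    slopes, scaled inverse-Wishart covariance prior) fitted by a
    purpose-built conjugate Gibbs sampler with truncated-normal censoring
    augmentation, Gelman-Rubin convergence diagnostics, and credible-interval
    summaries with percent-change contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
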