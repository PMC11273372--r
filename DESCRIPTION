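Package: micsel
Title: Correlated Responses of the Gut Microbiome to Divergent Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting correlated responses of a gut
    microbiome to divergent selection on a host phenotype (intramuscular
    fat in rabbit lines). Provides compositional preprocessing (prevalence
    filtering, Bayesian-multiplicative zero imputation, additive log-ratio
    transformation with data-driven reference selection, sequencer-batch
    correction), adjusted Shannon diversity with Kruskal-Wallis line
    comparison, microbiability estimation via a Bayesian microbiome-BLUP
    Gibbs sampler, cross-model-validated PLS and PLS-DA taxon selection
    with VIP scores and permutation tests, per-taxon Bayesian effect sizes
    with highest-posterior-density intervals, and a greedy log-contrast
    (balance) biomarker search with cross-validated logit classification.
    A synthetic-data generator with known ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    vegan,
    mixOmics
Config/testthat/edition: 3
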