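Package: plsmc
Title: Partial Least Squares and Monte Carlo Gene Selection for Continuous Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene selection for expression studies with a continuous phenotype
    (such as a disease severity index) by PLS1 regression fitted with the
    NIPALS algorithm. Genes are screened by variable importance on the
    projection (VIP) with a permutation-based empirical false discovery rate,
    the number of latent variables is chosen by k-fold root mean square error
    of cross-validation (RMSECV), and candidate genes are refined by the
    Monte Carlo regression-coefficient reliability (mean-to-standard-deviation
    ratio across half-sample refits) with an RMSECV-optimised reliability
    cutoff. Downstream helpers provide hypergeometric over-representation
    analysis against a flat gene-to-term annotation, degree/hub analysis of an
    interaction network over the selected genes with Cytoscape-compatible
    export, a synthetic-data generator with planted associations, and a
    one-call pipeline with a machine-readable run summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
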