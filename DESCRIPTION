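Package: momsub
Title: Multi-Omics Molecular Subtyping of Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative genomic and epigenomic subtyping of tumor cohorts
    from matched expression, copy-number and DNA-methylation profiles.
    Identifies copy-number-correlated (CNVcor) and methylation-correlated
    (METcor) genes by Pearson correlation with Fisher Z variance
    stabilization and survival filtering, derives molecular subtypes by
    Brunet-style KL-divergence NMF consensus clustering with cophenetic
    model selection, fits a lasso-penalized Gaussian latent-variable model
    across omics layers for joint integrative clustering, quantifies
    per-sample copy-number and methylation aberration-frequency coupling,
    and characterizes subtypes by survival, categorical omics differentials
    and mutation enrichment. Ships a seeded synthetic multi-omics cohort
    generator with planted subtype structure so every stage has a recovery
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    survival,
    cluster,
    mclust,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
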