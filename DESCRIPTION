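Package: e2response
Title: Window-of-Opportunity Estrogen Response Analysis for ER+ Breast Cancer
Version: 0.1.0
Authors@R:
    person("Window Trial", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for short pre-surgical ("window of opportunity")
    estrogen treatment studies in ER+/HER2- breast cancer. Provides paired
    pre/post-treatment biomarker statistics (Ki67 and Risk-of-Recurrence score
    changes, geometric-mean percent change, paired log t-tests, direction
    concordance kappa) and responder classification; derivation of responder
    vs non-responder gene-expression signatures by fold-change prefiltering
    followed by iterative bagged-tree (random forest) importance pruning and
    correlation-cluster refinement; cross-cohort response scoring by quantile
    normalization to a training reference and leaf-fraction scoring from the
    bagged ensemble; Kaplan-Meier / log-rank survival validation of score
    splits; gene-set overlap statistics (hypergeometric upper tail, Yates
    chi-square), promoter motif scanning and TSS-window peak annotation; and
    a negative-binomial synthetic-data generator that emulates paired
    core/surgical RNA-seq designs with a planted late-cell-cycle signature.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
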