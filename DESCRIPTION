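Package: homico
Title: Integration of Paired Host Transcriptome and Gut Microbiome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A workflow for mining associations between host gene expression
    and gut microbial composition in paired case/control cohorts. Group-level
    association uses sparse canonical correlation analysis via penalized matrix
    decomposition with leave-one-out grid tuning and held-out significance
    testing; feature-level association uses gene-wise lasso regression with
    desparsified (debiased) inference and stability selection under a perturbed
    penalty; pathways are scored with Fisher exact enrichment and a
    differential log-odds z statistic; shared and disease-specific gene-taxon
    association networks are mined across cohorts. A synthetic-data module
    generates paired multi-omic datasets with planted ground truth (latent
    shared factors, sparse per-gene taxon effects, enriched pathways) so every
    stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    vegan,
    igraph,
    jsonlite,
    fgsea,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    DESeq2,
    withr
Config/testthat/edition: 3
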