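Package: radsig
Title: Radiation-Specific Inflammatory Gene Expression Signatures in Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of targeted inflammatory gene expression panels
    (nCounter-style count data) in blood from radiotherapy patients and
    healthy donors. Implements signal-log-ratio contrasts classified by a
    one-dimensional Gaussian mixture model with BIC component selection and
    maximum-posterior up/similar/down calls; donor-variability assessment by
    complete-linkage hierarchical clustering on Spearman distances; paired
    differential expression with Cohen's d effect-size qualification and
    cross-cohort signature integration; empirical-Bayes batch correction with
    PCA component selection and UMAP embedding; and MQRT-PCR standard-curve
    relative quantification with a parametric/nonparametric decision-tree
    test per timepoint. Ships a synthetic-data generator with planted ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    sva
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape,
    optparse
SystemRequirements: Python (>= 3.8) with numpy and umap-learn on the PATH
    (used only by umap_embed()).
Config/testthat/edition: 3
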