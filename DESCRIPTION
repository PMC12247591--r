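Package: connectopath
Title: Weighted Path-Length Analysis of Structural Brain Connectomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Graph-theoretic analysis of anatomical brain networks built from
    tract-count connectivity matrices. Converts tract counts to inverse-weight
    distance matrices and computes weighted characteristic path length,
    clustering coefficient, global efficiency and small-worldness (with
    degree-preserving rewiring null models); simulates synthetic connectome
    cohorts with configurable group effects and symptom-correlation structure;
    runs the covariate-adjusted group-comparison, trend-test, partial-Spearman,
    FDR and regression battery; and performs ROC discrimination analysis with
    DeLong confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
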