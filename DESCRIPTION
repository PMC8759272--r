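Package: stageRewire
Title: Stage-Specific Co-Expression Re-Wiring Analysis for Cancer Progression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential co-expression ("re-wiring") analysis of cancer
    progression across tumour stages. Builds per-stage differential
    co-expression networks from RNA-seq counts, extracts co-expression
    modules by hybrid hierarchical clustering, quantifies stage specificity
    with permutation-based Zsummary/Medianrank preservation statistics,
    prioritises modules with a composite disease-relation score, fits a
    proportional-hazards risk model with VIF-based covariate pruning and
    quartile risk stratification, classifies stage-expression trends, and
    classifies gained, lost and reversed co-expression edges between
    consecutive stages. Ships a seeded multi-stage count simulator with
    planted module re-wiring, annotations and survival effects so that the
    whole pipeline can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    survival,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, Network, Survival, DifferentialExpression,
    GraphAndNetwork
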