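Package: hierMIL
Title: Hierarchical Attention Multiple Instance Learning for Patient
    Phenotype Prediction from Annotated Single-Cell Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts patient-level phenotype labels from annotated
    single-cell expression data with attention-based multiple instance
    learning that respects the cell-type hierarchy. Two models are
    provided: cell-type attention (CTA; mean pooling of cells within a
    type, attention over types) and hierarchical attention (HA; attention
    over cells within a type, then over types), plus mean-pooling and
    flat cell-attention ablations. Because pooling and the classification
    head are linear, prediction logits decompose exactly into per-cell
    and per-cell-type contributions; a class-contrast importance score
    with a label-permutation test and multiple-testing correction
    identifies critical cell types. Includes repeated nested
    cross-validation with inner-loop hyperparameter selection, robustness
    experiments (training size, cell subsampling, annotation noise), a
    seeded synthetic-cohort generator, and CSV/MTX cohort input/output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    SingleCellExperiment,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
biocViews: SingleCell, Classification, Transcriptomics, Software
RoxygenNote: 7.3.3
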