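Package: dbpFSE
Title: Feature-Selection Ensembles for DNA-Binding Protein Classification
    from Residue-Level Representations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts residue-level protein representation matrices
    (alignment-based position-specific scoring matrices or pretrained
    per-residue language-model embeddings, both L x d) into a unified
    29*d sequence-level feature set through four averaging operators
    (all-residue average, k-separation averages, per-amino-acid-type
    averages, and lagged squared-difference correlations), runs a staged
    feature-selection protocol (variance, chi-squared, maximal
    information coefficient, embedded coefficient/importance rankings,
    sparse-regularizer supports, and recursive feature elimination with
    cross-validation) under stratified five-fold cross-validation, and
    aggregates the trained models into an accuracy-weighted soft-voting
    ensemble for DNA-binding-protein classification. Includes a
    synthetic-data generator with planted class signal and a PSI-BLAST
    ASCII PSSM reader/writer so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    glmnet,
    ranger,
    xgboost,
    rpart,
    class,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Proteomics,
    SupportVectorMachine, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'classifiers.R'
    'dbpFSE-package.R'
    'evaluation.R'
    'ensemble.R'
    'repio.R'
    'features.R'
    'lars.R'
    'selection.R'
    'pipeline.R'
    'synthetic.R'
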