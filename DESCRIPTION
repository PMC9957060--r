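Package: GeneFamSelect
Title: NMF-ReliefF Feature Selection for Gene-Family Count Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds species-by-gene-family copy-number matrices from genome
    annotation and family-assignment tables, and selects class-informative
    features from high-dimensional nonnegative matrices by combining
    nonnegative matrix factorization (multiplicative Frobenius updates) with
    ReliefF instance-based feature weighting. Includes baseline selectors
    (ReliefF, PCA-ReliefF, SVM-RFE with an mRMR prefilter), a repeated
    stratified cross-validation harness reporting accuracy, sensitivity,
    specificity and pairwise AUC, and a synthetic-data generator with planted
    informative features for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    e1071,
    randomForest,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: FeatureExtraction, Classification, DimensionReduction, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
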