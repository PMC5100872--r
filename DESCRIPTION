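Package: genospace
Title: Training-Set Construction by Uniform Coverage of the Genetic Space
    for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and benchmarks training sets for genomic prediction on
    structured genotype panels. Implements five training-set construction
    methods (uniform coverage of the genetic space, stratified-uniform,
    optimization of the generalized coefficient of determination,
    log-proportional stratified, and random sampling), the marker-based
    relationship matrices they rely on (identity-by-state, Astle-Balding
    additive, Gaussian kernel, leave-one-chromosome-out and QTL-masked
    kinships), population-structure diagnostics (PCA of the IBS matrix with
    Tracy-Widom significance, k-means subpopulation assignment, and the
    Weir-Cockerham Fst estimator), a REML/BLUP mixed-model engine powering
    association scans with Li-Ji multiple-testing correction and four
    prediction models (multi-QTL, GBLUP, QTL+GBLUP, and Gaussian-kernel
    RKHS), Fisher-z aggregation of predictive ability over replicated
    splits, and a Balding-Nichols simulator of structured inbred panels
    with known genetic architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
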