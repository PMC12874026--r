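Package: emtax
Title: Multi-Axis Gene-Set Scoring of Epithelial-Mesenchymal Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies epithelial-mesenchymal transition (EMT) from bulk or
    single-cell expression matrices. Implements five single-sample gene-set
    scoring algorithms (nonnegative PCA with covariance deflation, ssGSEA,
    AUCell-style recovery curves, SCSE normalized sums, and JASMINE
    rank/odds-ratio scores). The nonnegative PCA default yields multiple
    ranked mesenchymal axes whose loadings expose divergent EMT programs.
    Downstream tools assign samples to E/hybrid/M states with a Gaussian
    mixture model in E-M score space, cross-tabulate states against sample
    labels, summarize scores over pseudotime, and screen gene-set collections
    for correlation with EMT progression. A seeded synthetic-data generator
    with planted E/M programs supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
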