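Package: ovsubtype
Title: Molecular Subtype Classification of High-Grade Serous Ovarian
    Carcinoma from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a differential-expression gene signature for the four
    molecular subtypes of high-grade serous ovarian carcinoma (differentiated,
    immunoreactive, mesenchymal, proliferative) from bulk RNA-seq counts,
    normalizes signature genes within each sample against stable control genes,
    and trains a four-channel fully connected neural network that classifies
    bulk samples, single cells, and spatial transcriptomics spots. Includes
    TMM/CPM normalization, Mann-Whitney and negative-binomial quasi-likelihood
    differential-expression tests with Benjamini-Hochberg correction, a
    synthetic count-data generator with planted subtype modules for end-to-end
    validation, and readers/writers for dense count tables, 10x-style sparse
    matrices, and Visium-style spatial folders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    pROC,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
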