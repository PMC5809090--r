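Package: osnclade
Title: Clade Classification and Sparse Discriminant Analysis of Olfactory
    Sensory Neuron Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-cell RNA-seq profiles of zebrafish
    olfactory sensory neurons (OSNs). Provides quality-control and maturity
    staging of single-cell transcriptomes, calling of the predominant odorant
    receptor (OR) per mature cell with assignment to one of three OR homology
    clades, median-of-ratios size-factor normalization and expression
    filtering, penalized (lasso) linear discriminant analysis to extract
    sparse clade-discriminating gene panels over configurable gene universes,
    stratified cross-validation of the sparse classifier, gene-gene
    correlation blocks, projection of bulk RNA-seq replicates onto the sparse
    single-cell feature space, and Fisher's exact quantification of axon
    protoglomerular targeting errors. Includes a synthetic-data generator
    reproducing the statistical structure of such experiments and the
    published per-cell OR expression table as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
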