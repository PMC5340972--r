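Package: immevo
Title: Immune Cell Transcriptomics and Evolutionary Divergence Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for single-cell RNA-seq of
    fluorescently sorted immune cells in a non-mammalian vertebrate, and for
    cross-species evolutionary analysis of the cell-type-specific genes it
    discovers. Covers cell quality control on TPM matrices, correlation-based
    dissimilarity with classical multidimensional scaling, empirical-Bayes
    batch adjustment, Ward clustering with silhouette-selected cluster number,
    marker-score cell typing, dropout-aware differential expression and
    signature construction, per-cell detection of TCR-beta V(D)J recombination
    from short reads (k-mer recruitment, greedy overlap assembly, local
    alignment annotation), ortholog-conservation permutation statistics, and
    classification of paralog pairs by duplication age and expression-pattern
    divergence (neofunctionalization). A synthetic-data module generates every
    input the pipeline consumes, with planted ground truth, so all stages are
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
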