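Package: phenotime
Title: Unsupervised Immunophenotyping of Tumor Immune Microenvironments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for profiling tumor immune
    microenvironments from cytometry and expression data. Implements
    PhenoGraph-style phenoclustering of flow and mass cytometry events
    (exact k-nearest-neighbour graph, Jaccard edge re-weighting and a
    from-scratch weighted Louvain modularity optimizer) in a two-round
    scheme with CD45-low cluster filtering and bootstrap-Jaccard cluster
    stability scoring; logicle and arcsinh intensity transforms with
    automatic parameter estimation; sample-by-phenocluster composition
    matrices with correlation statistics; reference-based bulk expression
    deconvolution by elastic-net regression; immune-gene-cluster activity
    scoring; and single-cell QC with per-cell-type overexpression
    subcluster analysis. A synthetic-data module with planted ground truth
    supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    glmnet,
    limma,
    cluster,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rtsne,
    uwot,
    mclust,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
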