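Package: spatialTME
Title: Spatial Single-Cell Analysis of Tumor Microenvironment Architecture
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-segmentation spatial analysis of multiplexed imaging data of
    the tumor microenvironment, developed around paired primary/recurrent
    glioblastoma imaging mass cytometry cohorts. Provides marker-based cell
    phenotyping on asinh-transformed intensities, subsampled Shannon-entropy
    diversity comparisons, pruned-Delaunay spatial graphs, permutation tests
    for pairwise cell-cell interaction and avoidance, cellular-neighborhood
    discovery by k-means on neighbor composition, spatial-context detection
    with dominance filtering, and centrality analysis of the resulting
    neighborhood interaction networks. A seeded synthetic-cohort generator
    with planted ground truth (cell types, states, composition shifts and
    adjacency enrichment) supports end-to-end validation without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    deldir,
    igraph,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
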