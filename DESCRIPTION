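Package: squirrelClust
Title: Quantum-Inspired Squirrel Search Feature Selection for
    Single-Cell Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature-selection-enhanced clustering of single-cell RNA-seq
    count matrices. A quantum-bit-encoded squirrel search metaheuristic
    explores gene subsets of the highly variable genes, scoring each
    candidate subset by K-means clustering quality (silhouette) balanced
    against subset size. The best subset feeds a final K-means (known K)
    or Louvain (K estimated from a nearest-neighbour graph) clustering,
    evaluated against reference labels with six external validity
    indices (RI, ARI, NMI, AMI, ACC, FMI). Includes a negative-binomial
    simulator with planted cell clusters and informative genes, a
    repeated-run driver with gene-selection-frequency aggregation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    FNN,
    clue,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
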