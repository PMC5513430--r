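Package: phamlin
Title: Comparative Genomics of Phage Collections: Phams, ANI, Clustering,
    and Gene-Content Diversity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for comparative analysis of annotated
    bacteriophage genomes. Groups predicted proteins into phamilies (phams)
    by pairwise amino-acid similarity with single-linkage clustering, computes
    fragment-based average nucleotide identity (ANI) and exact-word dotplots
    between genomes, assigns genomes to clusters and singletons from ANI and
    shared-gene-content evidence, builds pham presence/absence matrices with
    Jaccard gene-content distances and NEXUS/newick exports, and reports
    per-cluster diversity statistics (cluster-identifier phams, orphams,
    inter-cluster and cross-host pham sharing). Includes a synthetic
    mosaic-genome generator with planted clusters, phams, orphams and GC
    targets so that every stage is testable against a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
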