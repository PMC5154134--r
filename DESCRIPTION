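Package: ontonet
Title: Ontology- and Network-Aware Interpretation of Genomic Summary Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Interprets genomic summary data (gene lists, GWAS SNPs,
    genomic regions) against user-supplied knowledge files. Provides
    ontology term enrichment with Fisher, hypergeometric and binomial
    tests and a tree-aware elimination procedure; redundancy filtering
    for flat term collections; information-content semantic similarity
    between annotated entities via the most informative common ancestor;
    SNP-to-gene scoring with linkage-disequilibrium expansion and
    distance-decay weighting; maximum-scoring subnetwork search on gene
    interaction networks; base-resolution and sampling-based enrichment
    of genomic region sets against annotation tracks; and cross-trait
    gene-score taxonomies via consensus neighbour-joining trees. A
    seeded synthetic-fixture generator makes every analysis testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    igraph,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
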