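# ontonet

Ontology- and network-aware interpretation of genomic summary data.

Modern genetic studies end with summary data — a list of
differentially expressed genes, GWAS SNPs with association p-values,
or a set of genomic regions — and the hard work of turning those into
biology starts there. `ontonet` interprets such lists against
user-supplied knowledge files (ontologies, term–entity annotations,
gene interaction networks, gene models, genomic annotation tracks),
with no bundled databases and no downloads: every input is a plain
text file in a standard format (OBO, GMT, BED, TSV edge lists), and a
seeded synthetic-fixture generator makes the whole package testable
offline.

## What it computes

**Term enrichment** (`enrich_terms`). For a term annotating *M* of
*N* background entities with *x* of *k* input entities, three tests:
Fisher's one-sided exact test *P(X ≥ x)* under
Hypergeometric(*N*, *M*, *k*); the strict hypergeometric tail
*P(X > x)*; and the binomial *P(Bin(k, M/N) ≥ x)* — ordered
hypergeometric < Fisher < binomial on enriched tables. Annotations
follow the true-path rule up the ontology DAG. In tree-aware mode,
terms are processed leaves→root and entities claimed by a significant
child are removed from its ancestors before testing, suppressing
parents whose signal merely restates a child's. Flat collections get
a redundancy filter (B flagged when >90% of B is covered by a more
significant A and >50% of A by B). FDR (Benjamini–Hochberg, default)
or FWER (Bonferroni) control.

**Semantic similarity** (`pair_similarity`, `similarity_network`).
Term specificity is the information content
IC(t) = −log₁₀(annotation frequency of *t*); term–term similarity is
the IC of the most informative common ancestor (MICA); entity–entity
similarity combines per-term best matches by the average, maximum or
complete (default) best-matching rule, yielding a weighted undirected
similarity network.

**SNP-modulated subnetworks** (`snp_subnetwork`). GWAS SNPs (plus LD
proxies at R² > 0.8, inheriting the lead's p) are scored
relative to the significance threshold,

    score = R² · (log₁₀((1−p)/p) − log₁₀((1−p_thresh)/p_thresh)),

genes take the maximum of nearby SNP scores decayed by
(1 − d/D)^λ within a window D, and a prize-collecting-Steiner-tree
heuristic (shift → collapse → MST over the metric closure → exact
subtree pruning) extracts the maximum-scoring connected gene
subnetwork, with bisection size control for a desired node count.

**Region enrichment** (`region_enrich`, `nearest_genes`). Region sets
(half-open, 0-based) against annotation tracks: an exact
base-resolution binomial test, or an empirical null that re-places
each interval uniformly in the background preserving length and
chromosome. `nearest_genes` maps regions to all gene models within a
distance gap for downstream gene-level enrichment.

**Trait taxonomy** (`build_score_matrix`, `consensus_taxonomy`).
Per-trait gene scores stack into a matrix; inter-trait distance is the
cumulative (L1) difference in gene scores; neighbour-joining trees
with gene-column bootstrap give a majority-rule consensus taxonomy
with per-edge supports, written as Newick.

## Worked example

Everything below runs on a synthetic fixture; the planted truth is
known, so you can see the methods work.

```r
library(ontonet)

fx <- generate_fixture(seed = 7, scale = "small")
# 50-term ontology, 200 genes, 500 SNPs, interaction network with a
# wired 5-gene module, annotation tracks; fx$truth records what was planted

res <- enrich_terms(fx$truth$signal_genes, fx$annotation,
                    dag = fx$dag, tree_aware = TRUE)
print(res, 3)
#> eterm: 33 terms tested (fisher test, 20 input entities, background 200, tree-aware)
#>   term_id    name nAnno nOverlap   fc         p     adj_p
#> 1    T050 term 50    20       20 10.0 6.197e-28 2.045e-26
#> 2    T010 term 10    12        3  2.5 1.048e-01 8.254e-01
#> 3    T035 term 35    12        3  2.5 1.048e-01 8.254e-01
#> ... and 30 more terms
```

The planted term T050 is recovered with a 10-fold enrichment
(20/20 input genes vs 20/200 in the background) at an exact tail
probability of 6.2×10⁻²⁸; its ancestors, significant in a flat
analysis only because they inherit T050's genes, are eliminated
(p ≈ 0.1 after their claimed members are removed).

```r
sub <- snp_subnetwork(fx$snps, fx$genes, fx$network, ld = fx$ld,
                      target_n = 5)
print(sub)
#> scored_subnetwork: 5 genes, 4 edges, total shifted score 8.4441 (baseline 1.95)
#> G099, G101, G103, G105, G107

fx$truth$module_genes
#> [1] "G099" "G101" "G103" "G105" "G107"
```

The five genes carrying planted genome-wide-significant SNPs
(p ≈ 10⁻¹⁰, giving SNP scores near 2.7) are recovered exactly.

A command-line interface with the same functionality is installed as
the `ontonet` script (subcommands `enrich`, `sim`, `subnet`,
`region-enrich`, `region-genes`, `taxonomy`, `fixture`; exit codes 0
success / 2 input error / 3 empty result).

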