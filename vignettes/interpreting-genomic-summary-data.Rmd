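---
title: "Interpreting genomic summary data with ontonet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting genomic summary data with ontonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontonet)
```

ontonet interprets three kinds of genomic summary data -- gene lists,
GWAS SNPs with association p-values, and genomic region sets -- against
user-supplied knowledge: ontologies with term-to-entity annotations,
gene interaction networks, gene models and genomic annotation tracks.
This vignette is the package's own account of the statistics it
implements, the parameters that matter, and the design decisions taken
where more than one reasonable construction existed.

## The ontology backbone

Every ontology, structured or flat, is represented as a rooted DAG of
terms with `is_a` edges (`ontology_dag()`, `read_obo()`). Flat term
collections such as pathway gene sets receive an artificial root
linking all terms, so one propagation and testing machinery serves
both. Only `is_a`-type relations are honoured; other OBO relation
types are ignored, because nothing downstream distinguishes edge
semantics -- the DAG is used solely for ancestor closure.

Annotation follows the true-path rule (`propagate_annotations()`): an
entity annotated to a term is implicitly annotated to every ancestor,
so a term's propagated annotation is the union of direct annotations
over its descendants. The information content of a term
(`term_ic()`) is $-\log_{10}$ of its propagated annotation frequency:
0 at the root, increasing towards the leaves. The most informative
common ancestor of two terms (`term_mica()`) maximises IC over the
intersection of the two ancestor sets. Equal-IC ties are frequent --
a parent annotating exactly the same entities as its child has the
same IC -- and resolve to the most specific candidate (largest
ancestor set), then lexicographically. Preferring the most specific
term keeps the reported ancestor aligned with what a curator would
name as the shared concept; a purely lexicographic rule can surface an
arbitrarily shallow ancestor of the natural answer.

The annotation universe defaults to all annotated entities (the root's
propagated set); an explicit background can be supplied wherever the
study design defines one (e.g. all assayed genes), which covers both
readings of what the universe of a SNP-level ontology should be.

## Enrichment: three counting tests and their ordering

For a term annotating $M$ of $N$ background entities, with $k$ input
entities of which $x$ carry the term, `term_test_p()` offers:

* **Fisher** (default): the one-sided exact test,
  $P(X \ge x)$ under Hypergeometric$(N, M, k)$;
* **hypergeometric**: the strict tail $P(X > x)$;
* **binomial**: sampling with replacement, $P(\mathrm{Bin}(k, M/N) \ge x)$.

Reading the hypergeometric variant as the strict tail and Fisher as
the inclusive tail is the only construction under which the three
tests order as *hypergeometric < Fisher < binomial* on enriched
tables, which is how their relative stringency is conventionally
described. That ordering is a theorem only for genuinely enriched
configurations: the test suite verifies it exhaustively over all
contingency tables with $N \le 15$ in which the observed overlap
exceeds its expectation by at least one entity ($x \ge kM/N + 1$).
For weakly enriched tables near the expectation the Fisher and
binomial tails can cross, which is a property of the distributions,
not of the implementation.

Terms are tested when their propagated annotation size within the
background lies in `[min_size, max_size]`, default `[10, 2000]` --
the conventional bounds that drop uninformatively small and broad
terms. Multiple testing is controlled by Benjamini--Hochberg FDR by
default (`adjust = "fdr"`) or Bonferroni FWER (`"fwer"`); the FDR
being the less stringent criterion, its adjusted values never exceed
the Bonferroni ones.

### Tree-aware elimination

With `tree_aware = TRUE`, `enrich_terms()` processes terms leaves to
root. Whenever a term tests significant at the elimination stage
(raw p below `alpha_elim`, default 0.05), the input entities in its
overlap are claimed: they are removed from both the annotation set and
the overlap of every ancestor before the ancestor is tested. A parent
whose signal is wholly inherited from a specific child is thereby
reduced to $x = 0$ and $p = 1$, and the enrichment table keeps the
specific, informative terms. The elimination threshold applies to the
*raw* p-value: the set of adjusted values is not yet known while the
leaf-to-root sweep is running, so thresholding adjusted values would
make the elimination depend on its own output. Counts, fold changes
and member lists in tree-aware mode are the post-elimination ones,
since those are the quantities the reported p-value tested.

### Redundancy filtering for flat collections

Flat collections restate the same gene sets at many granularities.
`filter_redundant()` scans significant records from most to least
significant; a record B is flagged redundant against an
already-retained, more significant A when more than `c1` (default
0.90) of B's members are covered by A **and** more than `c2` (default
0.50) of A's members are covered by B. The second criterion protects
small, specific subsets of a broad term from being discarded -- they
describe a different granularity, not the same knowledge. Flagged
records stop serving as comparators; comparing against retained
records only keeps the scan order-deterministic (ties in p break by
term id) and prevents a chain of mutually redundant terms from
suppressing an informative one. Raising `c1` can only reduce the
number flagged; above 1 nothing is flagged.

## Semantic similarity

Similarity between two annotated entities derives from their
annotation profiles. For each term directly annotating one entity,
the best match is the maximal MICA IC against the other entity's
direct terms; the directional best-match vectors combine by one of
three rules (`pair_similarity()`):

* **average** -- the mean of the two directional averages;
* **maximum** -- the larger of the two directional averages;
* **complete** (default) -- the minimum over the union of all
  best-match values.

The formulas run over the *direct* term sets. This is deliberate:
every ancestor-closed profile contains the root, whose IC is 0, so a
complete rule evaluated over closed profiles would return 0 for every
pair and the method would be vacuous. The direct reading also matches
the natural count of "terms annotating an entity" (inherited terms are
retained in `entity_profile()` for reporting only; MICA and IC of
course still use the full DAG and propagated frequencies). The
complete rule is the default because it is insensitive to how many
terms annotate an entity: adding a further term whose best match is at
or above the current minimum changes the average but not the complete
score. Entities sharing only the root score 0 under all three rules.

`similarity_network()` computes all pairwise scores (caching the
term-term MICA table over the union of direct terms), emits an
undirected weighted edge list without self-edges, and can retain only
the `top_k` strongest edges or, at output time, only edges touching a
focus entity.

## From GWAS SNPs to a gene subnetwork

The SNP-level pipeline (`snp_subnetwork()`) composes three stages.

**LD expansion** (`ld_expand()`). Proxies with $R^2$ above `r2_min`
(default 0.8, exclusive) join the lead SNPs. A proxy inherits its
lead's p-value -- the association evidence at a proxy is the lead's
signal attenuated by LD, which is exactly what the $R^2$ factor in the
scoring formula expresses; carrying an independent proxy p-value would
double-count the locus. A proxy linked to several leads is kept once,
attached to its most significant lead (ties: maximal $R^2$).

**SNP scoring** (`snp_score()`), relative to the genome-wide
significance threshold `p_thresh` (default $5\times10^{-8}$):

$$\mathrm{score} = R^2\left(\log_{10}\frac{1-p}{p} -
\log_{10}\frac{1-p_\mathrm{thresh}}{p_\mathrm{thresh}}\right)$$

The formula is negative for sub-threshold SNPs; scores are truncated
at 0 so that such SNPs contribute nothing -- prizes must be
non-negative for "enriched in the most significant genes" to be
meaningful. P-values are floored at `p_floor` ($10^{-300}$) so values
printed as 0 stay finite.

**Gene scoring** (`gene_scores()`). A SNP within distance $d \le D$ of
a gene span (0 inside the span, measured to the nearest span edge,
gene spans rather than TSSs) contributes
$\mathrm{score}_\mathrm{SNP}(1-d/D)^\lambda$; the gene keeps the
maximum over contributing SNPs, so of many interdependent SNPs in one
region only the most informative counts. Defaults: window
$D = 50{,}000$ bases and decay $\lambda = 2$ -- a conservative
near-gene weighting under which a SNP 25 kb away retains a quarter of
its score; both are exposed on the function and the CLI.

**Subnetwork search** (`subnetwork_search()`). Node scores are shifted
by a `baseline` (default: the median positive score, making roughly
half the scored genes prizes and the rest penalties), and a heuristic
for the prize-collecting Steiner tree objective runs: adjacent
positive nodes collapse into meta-nodes; meta-nodes are connected by
cheapest linker paths (edge cost: mean penalty of the flanking
nodes) through a minimum spanning tree over the metric closure; the
expanded tree is pruned by exact best-subtree dynamic programming, so
no strictly-negative leaf survives and the result is always connected
and at least as good as the best single prize component. Correctness
is anchored behaviourally: on random graphs small enough for
exhaustive search the heuristic never exceeds and usually attains the
optimum (the acceptance suite quantifies this on 200 instances of at
most 10 nodes).

When a `target_n` is requested, the baseline is adjusted by bisection
on $[0, \max \mathrm{score}]$ -- the subnetwork shrinks as the
baseline rises -- for at most 20 steps; if the exact size is
unattainable (sizes jump when a linker drops out) the nearest
achievable size is returned with a warning.

## Region-set enrichment

Regions are half-open, 0-based intervals (BED convention) and are
merged before any arithmetic, so duplicated input cannot double-count
bases; strand is ignored. The default background is the union of the
annotation tracks -- the annotatable genome -- and input outside the
background is clipped with a warning.

* **Binomial mode**: at base resolution, each of the $n$ input bases
  within the background is a trial hitting a track of $m$ background
  bases with probability $q = m/|\mathrm{background}|$; the p-value is
  the exact upper tail $P(\mathrm{Bin}(n, q) \ge \mathrm{observed})$.
  Trials count bases, not regions, which is what "base resolution"
  means here.
* **Sampling mode**: each merged input interval is re-placed uniformly
  at random in the background $B$ times (default 2000), preserving its
  length and, where the background contains its chromosome, its
  chromosome -- respecting chromosome composition without inventing a
  finer null; intervals from chromosomes absent from the background
  place anywhere. Segments are chosen with probability proportional to
  the number of admissible start positions, so placement is uniform
  over all positions. The empirical p-value is
  $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(B+1)$, never exactly 0,
  and a z-score against the null mean and SD is reported. On a
  contiguous background with short intervals the null mean converges
  to the binomial expectation $nq$ -- the acceptance suite checks the
  two modes against each other within Monte-Carlo error.

The per-iteration null overlaps are computed by a cumulative-coverage
lookup on the merged track boundaries rather than by re-building
interval objects; unit tests pin this fast path to the reference
interval intersection.

`nearest_genes()` maps each region to **all** gene models within the
distance `gap` (overlap counts as 0), not the single closest gene:
pooled-gene analyses downstream want every gene a region may regulate,
and a single-nearest rule would silently drop equidistant candidates.
The pooled gene set feeds directly into `enrich_terms()`.

## Cross-trait taxonomy

Per-trait gene score maps stack into a trait-by-gene matrix
(`build_score_matrix()`, absent scores 0, labels sorted). The
distance between two traits is the cumulative difference in gene
scores, i.e. the L1 distance over the gene union -- the only
arithmetic the phrase "cumulative difference" supports, and a genuine
metric. Trees are built by standard Saitou--Nei neighbour joining
(exact on additive distances); negative branch lengths, which NJ
produces on non-additive input, are clamped to 0 with the deficit
transferred to a sibling edge so the sibling pair's path length is
preserved.

"Consensus" is constructed as a gene-column bootstrap: columns are
resampled with replacement $B$ times (default 100), the NJ tree is
rebuilt per replicate, and the majority-rule consensus topology
carries per-edge support fractions. Columns are canonically sorted by
gene label before resampling, so the result depends only on matrix
content and seed. All scored genes enter by default; a
`--min-score` filter is available on the CLI for users who prefer a
significance-restricted matrix, since either convention is defensible.
The tree is emitted unrooted; rooting is presentation.

## The synthetic fixture generator

`generate_fixture(seed, scale)` builds the package's test worlds:
a random rooted DAG with multi-parent terms; genes annotated to 1--3
terms with one planted leaf term carrying a dedicated signal set; gene
models laid out on 1--3 chromosomes at fixed spacing; a
preferential-attachment interaction network with a wired, genome-
adjacent 3--5 gene module; uniform GWAS p-values with one genome-wide
significant SNP ($p = 10^{-9.5}$ to $10^{-12}$) inside each module
gene; LD proxies straddling the 0.8 retention cutoff; and
block-structured annotation tracks with input regions partly planted
in the first track. Scales: `tiny` (12 terms / 10 genes / 8 SNPs;
small enough for exhaustive oracles), `small` (50 / 200 / 500),
`medium` (200 / 2000 / 5000). The planted signal set of 20 genes at
`small` makes the enriched term's exact tail probability around
$10^{-27}$, so recovery failures indicate bugs, not bad luck.

What the generator emulates is the *statistical shape* of real inputs;
what it does not emulate is their dependence structure: real LD blocks
correlate many SNPs, real ontologies have correlated annotation depth,
real interaction networks have community structure beyond preferential
attachment, and real annotation tracks follow chromatin domains.
Passing tests therefore demonstrate correctness of the computations
and calibration under clean nulls, not biological performance on real
cohorts.

## Numerical choices and degenerate inputs

* Tails are computed on log-safe library routines (`phyper`, `pbinom`)
  rather than explicit point-mass sums; oracles in the tests do the
  explicit sums and agree to $10^{-12}$.
* Terms with $M = 0$ after elimination report $p = 1$ rather than
  being dropped, so tree-aware output keeps one row per eligible term.
* All orderings (records, edges, tree tie-breaks, term ties) are
  deterministic: stable sorts keyed by p then identifier.
* `ld_expand()` drops proxies without positions (warning with count);
  `region_enrich()` errors on an empty background and on sampling
  intervals that fit no background segment; `subnetwork_search()`
  errors when no node clears the baseline, naming the baseline.
* Seeds: every stochastic entry point takes an explicit seed
  (`region_enrich`, `consensus_taxonomy`, `generate_fixture`, CLI
  `--seed`); the fixture generator restores the caller's RNG state.

## Problem sizes used by the test and acceptance suites

Exhaustive table enumeration to $N \le 15$ (716 enriched tables);
1000 random tables for the Fisher oracle; null calibration with 500
random sets per size in {10, 50, 200} on the small fixture; 200
random graphs of 5--10 nodes against the exhaustive subnetwork oracle
plus 50 planted small fixtures; sampling nulls at $B = 2000$; 100
random matrices for the metric axioms. These sizes make every
stochastic bound a multiple-sigma test rather than a coin flip while
keeping the whole suite in the low minutes on one CPU.

## Known limitations

* Elimination implements the classic leaf-to-root variant with a
  fixed raw-p threshold; conditional or weighted decorrelation schemes
  are out of scope.
* The subnetwork heuristic is tree-based; it can miss optima whose
  best connector is not on any cheapest path (observed on a few
  percent of random instances, always scoring below, never above, the
  exhaustive optimum).
* LD must be supplied; the package does not compute $R^2$ from
  genotypes, convert genome builds, or bundle any curated resource.
* Visualisation is limited to plain-text exports (TSV, DOT, Newick).
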