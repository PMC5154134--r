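test_that("SNP scoring matches the closed form and its boundaries", {
  ## threshold cancels exactly
  expect_equal(snp_score(5e-8), 0)
  ## direct hand evaluation at p = 1e-10
  expect_equal(snp_score(1e-10),
               log10((1 - 1e-10) / 1e-10) - log10((1 - 5e-8) / 5e-8),
               tolerance = 1e-12)
  expect_equal(snp_score(1e-10), 2.69897, tolerance = 1e-4)
  ## linear in R^2
  expect_equal(snp_score(1e-10, r2 = 0.5), snp_score(1e-10) / 2)
  ## sub-threshold SNPs contribute nothing
  expect_equal(snp_score(c(1e-7, 0.5, 1)), c(0, 0, 0))
  ## strictly decreasing in p below the threshold
  p_grid <- 10^seq(-300, log10(5e-8), length.out = 50)
  expect_true(all(diff(snp_score(p_grid)) < 0))
  ## flooring keeps the score finite
  expect_true(is.finite(snp_score(1e-320)))
  expect_error(snp_score(0), "must lie")
  expect_error(snp_score(1.5), "must lie")
})

test_that("LD expansion retains strong proxies with the lead's p-value", {
  leads <- data.frame(snp = c("L1", "L2"), chrom = "chr1",
                      pos = c(100L, 900L), p = c(1e-10, 1e-9))
  ## no proxies
  expect_identical(nrow(ld_expand(leads, NULL)), 2L)
  ## r2 cutoff is exclusive at 0.8: 0.9 kept, 0.7 dropped
  ld <- data.frame(lead = c("L1", "L1"), proxy = c("P1", "P2"),
                   r2 = c(0.9, 0.7))
  pos <- data.frame(snp = c("P1", "P2"), chrom = "chr1",
                    pos = c(150L, 160L))
  out <- ld_expand(leads, ld, pos)
  expect_setequal(out$snp, c("L1", "L2", "P1"))
  expect_equal(out$p[out$snp == "P1"], 1e-10)     # inherits the lead's p
  expect_equal(out$r2[out$snp == "P1"], 0.9)
  expect_equal(out$r2[out$snp %in% c("L1", "L2")], c(1, 1))
  ## proxy tied to two equally significant leads keeps the larger r2
  leads2 <- data.frame(snp = c("L1", "L2"), chrom = "chr1",
                       pos = c(100L, 900L), p = c(1e-9, 1e-9))
  ld2 <- data.frame(lead = c("L1", "L2"), proxy = c("P1", "P1"),
                    r2 = c(0.85, 0.95))
  out2 <- ld_expand(leads2, ld2, pos)
  expect_identical(sum(out2$snp == "P1"), 1L)
  expect_equal(out2$r2[out2$snp == "P1"], 0.95)
  ## with unequal leads the most significant lead wins
  leads3 <- data.frame(snp = c("L1", "L2"), chrom = "chr1",
                       pos = c(100L, 900L), p = c(1e-12, 1e-9))
  out3 <- ld_expand(leads3, ld2, pos)
  expect_equal(out3$p[out3$snp == "P1"], 1e-12)
  expect_equal(out3$r2[out3$snp == "P1"], 0.85)
  ## proxies without positions are dropped with a warning
  expect_warning(
    out4 <- ld_expand(leads, ld, pos[pos$snp == "P2", , drop = FALSE]),
    "without a known position")
  expect_false("P1" %in% out4$snp)
})

test_that("gene scoring keeps the most informative in-window SNP", {
  genes <- data.frame(gene = "G1", chrom = "chr1",
                      start = 10000L, end = 12000L)
  D <- 50000
  ## SNP inside the span: decay factor 1
  s_in <- data.frame(snp = "a", chrom = "chr1", pos = 11000L, p = 1e-10)
  expect_equal(gene_scores(s_in, genes, window = D)[["G1"]],
               snp_score(1e-10))
  ## SNP at exactly d = D contributes 0
  s_edge <- data.frame(snp = "b", chrom = "chr1", pos = 12000L + D,
                       p = 1e-10)
  expect_length(gene_scores(s_edge, genes, window = D), 0L)
  ## MAX scheme: a nearer weaker SNP beats a decayed stronger one
  ## (scores 3.0 at d = 0 vs 5.0 decayed by 0.4 -> 2.0)
  p_for <- function(target) (1 + 10^target)^-1  # p with log10((1-p)/p) = target
  p3 <- p_for(3 + log10((1 - 5e-8) / 5e-8))
  p5 <- p_for(5 + log10((1 - 5e-8) / 5e-8))
  expect_equal(snp_score(p3), 3, tolerance = 1e-9)
  d_at_04 <- D * (1 - sqrt(0.4))          # lambda = 2 decay of 0.4
  s_two <- data.frame(snp = c("near", "far"), chrom = "chr1",
                      pos = c(11000L, as.integer(12000L + d_at_04)),
                      p = c(p3, p5))
  expect_equal(gene_scores(s_two, genes, window = D)[["G1"]], 3,
               tolerance = 1e-3)
  ## invariant under SNP reordering
  expect_equal(gene_scores(s_two[2:1, ], genes, window = D),
               gene_scores(s_two, genes, window = D))
  ## monotone non-increasing in distance for a fixed SNP
  dists <- c(0, 1000, 10000, 30000, 49999)
  sc <- vapply(dists, function(d) {
    s <- data.frame(snp = "a", chrom = "chr1", pos = 12000L + d,
                    p = 1e-10)
    gene_scores(s, genes, window = D)[["G1"]]
  }, 1)
  expect_true(all(diff(sc) < 0))
  expect_error(gene_scores(s_in, genes, window = -1), "positive")
})

test_that("subnetwork search handles stars, linkers and stays connected", {
  ## star with a high centre and negative leaves: centre alone
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:5)
  res <- subnetwork_search(star, c(v1 = 5, v2 = -1, v3 = -1, v4 = -1,
                                   v5 = -1), baseline = 0)
  expect_identical(res$members, "v1")
  ## two prizes joined via one mildly negative hub: hub recruited as a
  ## linker (exhaustive optimum on this 5-node fixture)
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "hub"), c("hub", "b"), c("hub", "c"), c("c", "d")),
    directed = FALSE)
  sc <- c(a = 4, b = 4, hub = -0.5, c = -2, d = 0.1)
  res2 <- subnetwork_search(g, sc, baseline = 0)
  expect_setequal(res2$members, c("a", "hub", "b"))
  expect_equal(res2$score, 7.5)
  ## connectivity and leaf-pruning invariants on random instances
  for (seed in 1:40) {
    rg <- random_scored_graph(sample(5:10, 1L), seed)
    res <- tryCatch(subnetwork_search(rg$graph, rg$scores, baseline = 0),
                    error = function(e) NULL)
    if (is.null(res)) next          # all-negative instance
    expect_true(igraph::is_connected(res$graph))
    deg <- igraph::degree(res$graph)
    leaf_scores <- res$node_scores[names(deg)[deg <= 1L]]
    if (length(res$members) > 1L) {
      expect_true(all(leaf_scores > 0))   # negative leaf would prune
    }
    ## never exceeds the exhaustive optimum
    opt <- oracle_best_subgraph(rg$adj, unname(rg$scores))
    expect_lte(res$score, opt$score + 1e-9)
    ## and never drops below the best single node
    expect_gte(res$score, max(rg$scores) - 1e-9)
  }
  expect_error(subnetwork_search(star, c(v1 = -1), baseline = 0),
               "baseline")
})

test_that("size control returns the requested subnetwork size", {
  fx <- generate_fixture(17, "small")
  res <- snp_subnetwork(fx$snps, fx$genes, fx$network, ld = fx$ld,
                        target_n = 5)
  expect_identical(length(res$members), 5L)
  expect_true(igraph::is_connected(res$graph))
  ## zero signal: every p at the threshold scores nothing
  flat <- fx$snps
  flat$p <- 5e-8
  expect_error(snp_subnetwork(flat, fx$genes, fx$network),
               "no gene received a positive score")
})

test_that("the planted SNP-modulated module is recovered end to end", {
  jac <- vapply(1:15, function(i) {
    fx <- generate_fixture(200 + i, "small")
    res <- snp_subnetwork(fx$snps, fx$genes, fx$network, ld = fx$ld,
                          target_n = length(fx$truth$module_genes))
    length(intersect(res$members, fx$truth$module_genes)) /
      length(union(res$members, fx$truth$module_genes))
  }, 1)
  expect_gte(mean(jac), 0.8)
})
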