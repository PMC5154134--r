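test_that("counting tests match hand values and independent tail sums", {
  ## empty overlap is never significant
  expect_equal(term_test_p(0, 5, 5, 20, "fisher"), 1)
  expect_equal(term_test_p(0, 5, 5, 20, "binomial"), 1)
  ## perfect 5-of-5 overlap in a 20-entity background
  expect_equal(term_test_p(5, 5, 5, 20, "fisher"), 1 / choose(20, 5))
  ## Fisher's one-sided p equals the inclusive hypergeometric tail sum
  ## and agrees with stats::fisher.test as an independent route
  set.seed(42)
  for (i in 1:200) {
    N <- sample(10:500, 1L); M <- sample.int(N - 1L, 1L)
    k <- sample.int(N, 1L)
    x <- sample(max(0L, k - (N - M)):min(M, k), 1L)
    expect_equal(term_test_p(x, M, k, N, "fisher"),
                 oracle_hyper_tail(x, M, k, N), tolerance = 1e-12)
    expect_equal(term_test_p(x, M, k, N, "binomial"),
                 oracle_binom_tail(x, k, M / N), tolerance = 1e-12)
  }
  tbl <- matrix(c(8, 2, 4, 16), 2, byrow = TRUE)
  expect_equal(term_test_p(8, 12, 10, 30, "fisher"),
               stats::fisher.test(tbl, alternative = "greater")$p.value,
               tolerance = 1e-12)
  ## strict tail is below the inclusive one whenever P(X = x) > 0
  expect_lt(term_test_p(3, 5, 5, 20, "hypergeometric"),
            term_test_p(3, 5, 5, 20, "fisher"))
  expect_error(term_test_p(6, 5, 5, 20), "invalid contingency")
})

test_that("multiple-testing adjustment follows BH and Bonferroni", {
  expect_equal(adjust_pvalues(0.02, "fdr"), 0.02)
  expect_equal(adjust_pvalues(0.02, "fwer"), 0.02)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "fdr"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.01, 0.5), "fwer"), c(0.02, 1.0))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1L))
    expect_true(all(adjust_pvalues(p, "fdr") <=
                    adjust_pvalues(p, "fwer") + 1e-15))
    expect_true(all(adjust_pvalues(p, "fdr") >= p))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "must lie")
})

test_that("flat enrichment counts match a brute-force recomputation", {
  ## 20-gene universe, two nested terms
  dag <- ontology_dag(rbind(c("inner", "outer"), c("outer", "root")))
  direct <- list(inner = paste0("g", 1:5),
                 outer = paste0("g", 6:10),
                 root = paste0("g", 11:20))
  ann <- propagate_annotations(dag, direct)
  input <- paste0("g", c(1:4, 8, 15))
  res <- enrich_terms(input, ann, dag = dag, min_size = 1, max_size = 100)
  for (i in seq_len(nrow(res))) {
    t <- res$term_id[i]
    M <- length(ann$propagated[[t]])
    x <- length(intersect(input, ann$propagated[[t]]))
    expect_identical(res$nAnno[i], M)
    expect_identical(res$nOverlap[i], x)
    expect_equal(res$p[i], oracle_hyper_tail(x, M, length(input), 20),
                 tolerance = 1e-12)
    expect_equal(res$fc[i], (x / 6) / (M / 20))
  }
  ## records sorted by ascending p; members populated
  expect_true(!is.unsorted(res$p))
  expect_identical(res$members[[1L]], paste0("g", 1:4))

  ## input exactly equal to one term's annotation attains minimal p
  res2 <- enrich_terms(paste0("g", 1:5), ann, dag = dag,
                       min_size = 1, max_size = 100)
  expect_identical(res2$term_id[1L], "inner")

  expect_error(enrich_terms("nothere", ann, dag = dag, min_size = 1),
               "match the annotation universe")
})

test_that("tree-aware elimination removes entities claimed by children", {
  fx <- chain_elim_fixture()
  ## parent overlap wholly contributed by a significant child
  res <- enrich_terms(paste0("g", 1:4), fx$ann, dag = fx$dag,
                      tree_aware = TRUE, min_size = 1, max_size = 100)
  leaf <- res[res$term_id == "leaf", ]
  mid <- res[res$term_id == "mid", ]
  top <- res[res$term_id == "top", ]
  expect_lt(leaf$p, 0.05)
  expect_identical(mid$nOverlap, 0L)
  expect_identical(top$nOverlap, 0L)
  expect_equal(mid$p, 1)
  expect_equal(top$p, 1)

  ## hand-worked elimination pass on the 10-entity fixture:
  ## input g1..g4,g5; leaf p = 6/252 triggers elimination, after which
  ## mid keeps only {g5,g6} (x=1, M=2) and top {g7..g10} (x=0)
  res2 <- enrich_terms(paste0("g", c(1:4, 5)), fx$ann, dag = fx$dag,
                       tree_aware = TRUE, min_size = 1, max_size = 100)
  expect_equal(res2$p[res2$term_id == "leaf"], 6 / 252,
               tolerance = 1e-12)
  expect_identical(res2$nAnno[res2$term_id == "mid"], 2L)
  expect_identical(res2$nOverlap[res2$term_id == "mid"], 1L)
  expect_equal(res2$p[res2$term_id == "mid"],
               1 - choose(8, 5) / choose(10, 5), tolerance = 1e-12)
  ## top keeps only the unclaimed g5 of its overlap: x=1 of M=6, and
  ## P(X >= 1) = 1 because drawing 5 from 10 with only 4 non-carriers
  ## always hits a carrier
  expect_identical(res2$nOverlap[res2$term_id == "top"], 1L)
  expect_identical(res2$nAnno[res2$term_id == "top"], 6L)
  expect_equal(res2$p[res2$term_id == "top"], 1)

  ## with no significant child anywhere the output equals flat mode
  res_flat <- enrich_terms(c("g5", "g8"), fx$ann, dag = fx$dag,
                           min_size = 1, max_size = 100)
  res_tree <- enrich_terms(c("g5", "g8"), fx$ann, dag = fx$dag,
                           tree_aware = TRUE, min_size = 1,
                           max_size = 100)
  expect_equal(res_flat$p, res_tree$p)
  expect_identical(res_flat$nOverlap, res_tree$nOverlap)
})

test_that("redundancy filter reproduces the three overlap scenarios", {
  mk <- function(term, p, members) {
    out <- data.frame(term_id = term, name = term,
                      nAnno = length(members),
                      nOverlap = length(members), fc = 1, p = p,
                      adj_p = p, flagged_redundant = FALSE,
                      stringsAsFactors = FALSE)
    out$members <- list(members)
    class(out) <- c("eterm", "data.frame")
    out
  }
  ## scenario 1: partial overlap, neither criterion met -> retained
  s1 <- rbind(mk("A", 1e-6, paste0("g", 1:20)),
              mk("B", 1e-4, paste0("g", 15:34)))
  ## scenario 2: B inside A with similar size -> flagged
  s2 <- rbind(mk("A", 1e-6, paste0("g", 1:20)),
              mk("B", 1e-4, paste0("g", 1:19)))
  ## scenario 3: B a small subset of a broad A -> retained (criterion 2)
  s3 <- rbind(mk("A", 1e-6, paste0("g", 1:20)),
              mk("B", 1e-4, paste0("g", 1:5)))
  expect_false(filter_redundant(s1)$flagged_redundant[2L])
  expect_true(filter_redundant(s2)$flagged_redundant[2L])
  expect_false(filter_redundant(s3)$flagged_redundant[2L])

  ## flagged records drop out as comparators: C overlaps flagged B
  ## but not retained A, so C survives
  s4 <- rbind(mk("A", 1e-6, paste0("g", 1:20)),
              mk("B", 1e-4, paste0("g", 1:19)),
              mk("C", 1e-3, paste0("g", 1:19)))
  f4 <- filter_redundant(s4)
  expect_identical(f4$flagged_redundant, c(FALSE, TRUE, TRUE))

  ## raising c1 can only reduce the number flagged; c1 > 1 flags none
  set.seed(11)
  for (i in 1:10) {
    recs <- do.call(rbind, lapply(1:6, function(j) {
      mk(LETTERS[j], j * 1e-4,
         sample(paste0("g", 1:30), sample(5:20, 1L)))
    }))
    n_flagged <- vapply(c(0.5, 0.7, 0.9, 1.01), function(c1) {
      sum(filter_redundant(recs, c1 = c1)$flagged_redundant)
    }, 1L)
    expect_true(all(diff(n_flagged) <= 0L))
    expect_identical(n_flagged[4L], 0L)
  }
})
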