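## Independent brute-force oracles. These deliberately avoid the
## package's internal data structures beyond reading raw inputs, so a
## bug in the implementation cannot hide in its own oracle.

## ancestors by naive repeated parent-walking over a child->parent edge
## matrix (term itself included)
oracle_ancestors <- function(edges, term) {
  out <- term
  repeat {
    up <- unique(edges[edges[, 1L] %in% out, 2L])
    new <- setdiff(up, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  sort(out)
}

## MICA by full intersection of ancestor sets; ties resolve to the
## most specific candidate (largest ancestor set), then lexicographic
oracle_mica <- function(edges, ic, t1, t2) {
  common <- intersect(oracle_ancestors(edges, t1),
                      oracle_ancestors(edges, t2))
  vals <- ic[common]
  vals[is.na(vals)] <- 0
  best <- max(vals)
  cand <- common[vals == best]
  depth <- vapply(cand, function(t)
    length(oracle_ancestors(edges, t)), 1L)
  list(term = sort(cand[depth == max(depth)])[1L], ic = unname(best))
}

## inclusive hypergeometric upper tail by point-probability summation
oracle_hyper_tail <- function(x, M, k, N) {
  hi <- min(M, k)
  if (x > hi) return(0)
  sum(stats::dhyper(x:hi, M, N - M, k))
}

## binomial upper tail by summation
oracle_binom_tail <- function(x, k, q) {
  if (x > k) return(0)
  sum(stats::dbinom(x:k, k, q))
}

## best-matching similarity by naive double loops over direct term sets
oracle_pair_similarity <- function(edges, ic, t1, t2, method) {
  bm <- function(from, to) {
    vapply(from, function(a) {
      max(vapply(to, function(b) oracle_mica(edges, ic, a, b)$ic, 1))
    }, 1)
  }
  b12 <- bm(t1, t2); b21 <- bm(t2, t1)
  switch(method,
    average = (mean(b12) + mean(b21)) / 2,
    maximum = max(mean(b12), mean(b21)),
    complete = min(c(b12, b21)))
}

## exhaustive maximum-scoring connected induced subgraph over all
## vertex subsets (bitmask enumeration; graphs of <= ~12 nodes)
oracle_best_subgraph <- function(adj, scores) {
  n <- length(scores)
  adj_mask <- vapply(seq_len(n), function(i)
    sum(2^(which(adj[i, ] > 0) - 1L)), 1)
  best <- -Inf; best_set <- integer(0)
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1L))) > 0)
    ## connectivity by frontier expansion on bitmasks
    reach <- 2^(members[1L] - 1L)
    repeat {
      grow <- reach
      for (v in members) {
        if (bitwAnd(reach, 2^(v - 1L)) > 0) {
          grow <- bitwOr(grow, bitwAnd(adj_mask[v], mask))
        }
      }
      if (grow == reach) break
      reach <- grow
    }
    if (reach != sum(2^(members - 1L))) next
    sc <- sum(scores[members])
    if (sc > best) { best <- sc; best_set <- members }
  }
  list(score = best, members = best_set)
}

## L1 distance computed directly
oracle_l1 <- function(a, b) sum(abs(a - b))

## -------- shared toy structures --------

## five-level toy ontology with two informative branches; four
## entities whose pairwise similarity has a known strict ordering
toy_similarity_fixture <- function() {
  edges <- rbind(
    c("T1.1", "T1"), c("T1.2", "T1"), c("T1.3", "T1"), c("T1.4", "T1"),
    c("T1.1.1", "T1.1"),
    c("T1.1.1.1", "T1.1.1"), c("T1.1.1.2", "T1.1.1"),
    c("T1.2.1", "T1.2"), c("T1.2.2", "T1.2"))
  dag <- ontology_dag(edges)
  direct <- list(
    "T1.1.1.1" = c("SNP1", "SNPC"),
    "T1.2.1" = c("SNP1", "SNPC"),
    "T1.1.1.2" = "SNPA",
    "T1.2.2" = "SNPA",
    "T1.3" = "SNPB",
    "T1.4" = "SNPB")
  ann <- propagate_annotations(dag, direct)
  list(dag = dag, edges = edges, ann = ann, ic = term_ic(ann))
}

## three-level chain ontology with a split signal for the elimination
## procedure: child's overlap wholly explains the parent's
chain_elim_fixture <- function() {
  dag <- ontology_dag(rbind(c("leaf", "mid"), c("mid", "top")))
  direct <- list(leaf = paste0("g", 1:4),
                 mid = paste0("g", 5:6),
                 top = paste0("g", 7:10))
  ann <- propagate_annotations(dag, direct)
  list(dag = dag, ann = ann)
}

## random rooted DAG over n terms (child picks 1-2 earlier parents)
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("R%02d", seq_len(n))
  edges <- NULL
  for (i in 2:n) {
    np <- if (i > 3 && runif(1) < 0.4) 2L else 1L
    pa <- sample(ids[seq_len(i - 1L)], min(np, i - 1L))
    edges <- rbind(edges, cbind(ids[i], pa))
  }
  list(dag = ontology_dag(edges, terms = ids), edges = edges, ids = ids)
}

## random connected-ish scored graph for subnetwork oracle tests
random_scored_graph <- function(n, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  ## random spanning tree guarantees connectivity, then extra edges
  for (i in 2:n) {
    j <- sample.int(i - 1L, 1L)
    adj[i, j] <- adj[j, i] <- 1L
  }
  extra <- which(upper.tri(adj) & adj == 0L)
  add <- sample(extra, min(length(extra), rbinom(1, n, 0.4)))
  adj[add] <- 1L
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  scores <- round(runif(n, -3, 3), 2)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  list(graph = g, adj = adj,
       scores = stats::setNames(scores, igraph::V(g)$name))
}
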