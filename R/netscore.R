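#' Score a GWAS SNP from its association p-value
#'
#' Converts a SNP p-value into a non-negative prize relative to a
#' genome-wide significance threshold, attenuated by linkage
#' disequilibrium for proxy SNPs:
#' \deqn{score = R^2 (\log_{10}\frac{1-p}{p} - \log_{10}\frac{1-p_{thresh}}{p_{thresh}})}
#' A SNP exactly at the threshold scores 0; sub-threshold SNPs would
#' score negative and are truncated to 0 so they contribute nothing
#' downstream. Lead SNPs use `r2 = 1`. P-values are floored at
#' `p_floor` to keep the score finite for values printed as 0.
#'
#' @param p p-value(s) in (0, 1].
#' @param r2 LD strength in \[0, 1\]; recycled.
#' @param p_thresh significance threshold (default `5e-8`, typical for
#'   GWAS).
#' @param p_floor minimum admissible p-value (default `1e-300`).
#' @return numeric vector of non-negative scores.
#' @examples
#' snp_score(1e-10)          # about 2.699
#' snp_score(5e-8)           # 0: threshold cancels
#' @export
snp_score <- function(p, r2 = 1, p_thresh = 5e-8, p_floor = 1e-300) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (p_thresh <= 0 || p_thresh >= 1) stop("p_thresh must lie in (0, 1)")
  p <- pmax(p, p_floor)
  lg <- function(q) log10((1 - q) / q)
  pmax(0, r2 * (lg(p) - lg(p_thresh)))
}

#' Expand lead SNPs with their LD proxies
#'
#' Retains proxies whose LD with a lead exceeds `r2_min` (default
#' `0.8`). Proxies inherit the p-value of their lead (their association
#' is attenuated through the `R^2` factor in [snp_score()]) and carry
#' their own genomic positions. A proxy linked to several leads is
#' emitted once, attached to its most significant lead (smallest p;
#' among ties, maximal r2). Proxies without a known position are
#' dropped, with a warning stating how many.
#'
#' @param snps data.frame of lead SNPs with columns `snp`, `chrom`,
#'   `pos`, `p` (positions 1-based).
#' @param ld data.frame with columns `lead`, `proxy`, `r2`; may be
#'   empty or `NULL`.
#' @param snp_positions optional data.frame (`snp`, `chrom`, `pos`)
#'   supplying proxy positions.
#' @param r2_min retention threshold on r2 (exclusive).
#' @return data.frame with columns `snp`, `chrom`, `pos`, `p`, `r2`
#'   (leads carry `r2 = 1`), sorted by snp id.
#' @export
ld_expand <- function(snps, ld = NULL, snp_positions = NULL, r2_min = 0.8) {
  stopifnot(all(c("snp", "chrom", "pos", "p") %in% names(snps)))
  leads <- data.frame(snp = snps$snp, chrom = snps$chrom, pos = snps$pos,
                      p = snps$p, r2 = 1, stringsAsFactors = FALSE)
  leads <- leads[!duplicated(leads$snp), ]
  out <- leads
  if (!is.null(ld) && nrow(ld)) {
    ld <- ld[ld$lead %in% leads$snp & ld$r2 > r2_min, , drop = FALSE]
    ld <- ld[!ld$proxy %in% leads$snp, , drop = FALSE]
    if (nrow(ld)) {
      ld$p <- leads$p[match(ld$lead, leads$snp)]
      ## one record per proxy: most significant lead, then maximal r2
      ld <- ld[order(ld$proxy, ld$p, -ld$r2, ld$lead), ]
      ld <- ld[!duplicated(ld$proxy), ]
      pos <- snp_positions
      if (is.null(pos)) pos <- snps[, c("snp", "chrom", "pos")]
      m <- match(ld$proxy, pos$snp)
      n_missing <- sum(is.na(m))
      if (n_missing > 0L) {
        warning(n_missing, " LD prox", if (n_missing == 1L) "y" else "ies",
                " without a known position dropped")
      }
      ok <- !is.na(m)
      if (any(ok)) {
        proxies <- data.frame(snp = ld$proxy[ok],
                              chrom = pos$chrom[m[ok]],
                              pos = pos$pos[m[ok]],
                              p = ld$p[ok], r2 = ld$r2[ok],
                              stringsAsFactors = FALSE)
        out <- rbind(out, proxies)
      }
    }
  }
  out <- out[order(out$snp), ]
  rownames(out) <- NULL
  out
}

#' Score genes by genomic proximity to scored SNPs
#'
#' Each SNP within distance `d <= window` of a gene span (distance 0
#' inside the span, measured to the nearest span edge otherwise)
#' contributes \eqn{score_{SNP} (1 - d/D)^{\lambda}}; the gene score is
#' the maximum over contributing SNPs, so of many interdependent SNPs
#' in one region only the most informative one counts. Genes with no
#' in-window SNP are absent from the result.
#'
#' @param snps data.frame with `snp`, `chrom`, `pos`, `p` and
#'   optionally `r2` (from [ld_expand()]; defaults to 1).
#' @param genes data.frame of gene models: `gene`, `chrom`, `start`,
#'   `end` (half-open, 0-based).
#' @param window maximum SNP-to-gene distance D in bases (default
#'   50000).
#' @param lambda decay exponent (default 2): larger values concentrate
#'   influence near the gene.
#' @param p_thresh,p_floor passed to [snp_score()].
#' @return named numeric vector of positive gene scores (genes whose
#'   best contribution is 0 are dropped), names sorted.
#' @export
gene_scores <- function(snps, genes, window = 50000, lambda = 2,
                        p_thresh = 5e-8, p_floor = 1e-300) {
  if (window <= 0) stop("the distance window must be positive")
  if (lambda < 0) stop("lambda must be non-negative")
  stopifnot(all(c("snp", "chrom", "pos", "p") %in% names(snps)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  r2 <- if ("r2" %in% names(snps)) snps$r2 else rep(1, nrow(snps))
  s <- snp_score(snps$p, r2, p_thresh, p_floor)

  gr_snp <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  ## half-open 0-based [start, end) -> 1-based closed [start+1, end]
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end))
  hits <- GenomicRanges::findOverlaps(gr_gene, gr_snp, maxgap = window)
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(gi) == 0L) return(stats::setNames(numeric(0), character(0)))
  ## d = 0 inside the span, else bases to the nearest span edge
  pos <- snps$pos[si]; gs <- genes$start[gi]; ge <- genes$end[gi]
  d <- pmax(0, pmax(gs + 1L - pos, pos - ge))
  keep <- d <= window
  gi <- gi[keep]; si <- si[keep]; d <- d[keep]
  if (length(gi) == 0L) return(stats::setNames(numeric(0), character(0)))
  contrib <- s[si] * (1 - d / window)^lambda
  sc <- tapply(contrib, genes$gene[gi], max)
  sc <- stats::setNames(as.numeric(sc), names(sc))
  sc <- sc[sc > 0]
  sc[order(names(sc))]
}

## best connected subtree of `tree` (an igraph tree) under vertex
## scores: f(v) = s(v) + sum over children of max(0, f(child));
## the maximising subtree is exact on trees
best_subtree <- function(tree, score) {
  n <- igraph::vcount(tree)
  nm <- igraph::V(tree)$name
  if (n == 1L) return(nm)
  d <- igraph::dfs(tree, root = 1, order = TRUE, father = TRUE)
  ordv <- as.integer(d$order)
  father <- as.integer(d$father)
  f <- unname(score[nm])
  keep <- vector("list", n)
  for (v in rev(ordv)) {             # leaves first
    p <- father[v]
    if (!is.na(p) && f[v] > 0) {
      f[p] <- f[p] + f[v]
      keep[[p]] <- c(keep[[p]], v)
    }
  }
  members <- integer(0)
  queue <- which.max(f)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    members <- c(members, v)
    queue <- c(queue, keep[[v]])
  }
  sort(nm[members])
}

## one pass of the shift-collapse-MST-prune heuristic at a fixed
## baseline; returns NULL when no node is positive after shifting
pcst_once <- function(graph, shifted) {
  vs <- igraph::V(graph)$name
  pos <- vs[shifted[vs] > 0]
  if (length(pos) == 0L) return(NULL)

  comp_all <- igraph::components(graph)
  best <- NULL; best_score <- -Inf
  for (cid in seq_len(comp_all$no)) {
    cvs <- vs[comp_all$membership == cid]
    if (!any(shifted[cvs] > 0)) next
    sub <- igraph::induced_subgraph(graph, cvs)
    svs <- igraph::V(sub)$name

    ## collapse adjacent positive nodes into meta-components
    possub <- svs[shifted[svs] > 0]
    pg <- igraph::induced_subgraph(sub, possub)
    pc <- igraph::components(pg)
    meta <- split(igraph::V(pg)$name, pc$membership)
    meta <- meta[order(vapply(meta, min, ""))]

    ## candidate: best single meta-component
    for (mcomp in meta) {
      sc <- sum(shifted[mcomp])
      if (sc > best_score) { best_score <- sc; best <- sort(mcomp) }
    }
    if (length(meta) > 1L) {
      ## connect meta-components through negative linkers: shortest
      ## paths under node penalties, then an MST over the metric
      ## closure, expanded and pruned by exact subtree optimisation
      pen <- pmax(0, -shifted[svs]); names(pen) <- svs
      ew <- apply(igraph::as_edgelist(sub), 1L,
                  function(e) (pen[[e[1L]]] + pen[[e[2L]]]) / 2)
      reps <- vapply(meta, `[[`, "", 1L)
      dmat <- igraph::distances(sub, v = reps, to = reps, weights = ew)
      dmat <- (dmat + t(dmat)) / 2            # exact symmetry
      mg <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                weighted = TRUE, diag = FALSE)
      mt <- igraph::mst(mg, weights = igraph::E(mg)$weight)
      nodes <- unlist(meta, use.names = FALSE)
      for (e in seq_len(igraph::ecount(mt))) {
        ends <- igraph::ends(mt, e)
        sp <- igraph::shortest_paths(sub, from = ends[1L], to = ends[2L],
                                     weights = ew)$vpath[[1L]]
        nodes <- c(nodes, igraph::V(sub)$name[as.integer(sp)])
      }
      nodes <- unique(nodes)
      stein <- igraph::induced_subgraph(sub, nodes)
      ## spanning tree of the Steiner subgraph, then exact best subtree
      tw <- apply(igraph::as_edgelist(stein), 1L,
                  function(e) (pen[[e[1L]]] + pen[[e[2L]]]) / 2)
      tree <- igraph::mst(stein, weights = tw)
      members <- best_subtree(tree, shifted)
      sc <- sum(shifted[members])
      if (sc > best_score) { best_score <- sc; best <- members }
    }
  }
  list(members = best, score = best_score)
}

#' Maximum-scoring connected subnetwork search
#'
#' Searches a node-scored gene interaction network for a connected
#' subnetwork enriched in highly scored genes while admitting a few
#' lower-scored genes as linkers -- a heuristic for the prize-collecting
#' Steiner tree objective. Scores are shifted by a `baseline` so that
#' low-scoring nodes become negative penalties; adjacent positive nodes
#' are collapsed, connected through cheapest linker paths via a
#' minimum spanning tree over the metric closure, and the expanded tree
#' is pruned by exact best-subtree optimisation, so no
#' strictly-negative leaf survives. The returned subgraph is connected
#' and its total shifted score is never below that of the best single
#' positive node.
#'
#' When `target_n` is given, the baseline is adjusted by bisection
#' (at most 20 steps) until the subnetwork has `target_n` nodes; if the
#' exact size is unattainable the nearest achievable size is returned
#' with a warning.
#'
#' @param graph an undirected [igraph::igraph] with named vertices.
#' @param scores named numeric vector of node scores; nodes absent from
#'   it score 0.
#' @param baseline score shift; default is the median positive score
#'   (roughly half the scored genes become prizes).
#' @param target_n optional desired subnetwork size.
#' @return object of class `scored_subnetwork`: list with `graph` (the
#'   induced subgraph), `members`, `score` (total shifted score),
#'   `baseline`, and `node_scores` (raw scores of members).
#' @export
subnetwork_search <- function(graph, scores, baseline = NULL,
                              target_n = NULL) {
  stopifnot(igraph::is_igraph(graph))
  if (is.null(igraph::V(graph)$name)) {
    stop("graph vertices must be named")
  }
  graph <- igraph::simplify(graph)
  vs <- igraph::V(graph)$name
  full <- stats::setNames(rep(0, length(vs)), vs)
  full[intersect(names(scores), vs)] <- scores[intersect(names(scores), vs)]

  run_at <- function(b) pcst_once(graph, full - b)

  if (is.null(target_n)) {
    if (is.null(baseline)) {
      posv <- full[full > 0]
      baseline <- if (length(posv)) stats::median(posv) else 0
    }
    res <- run_at(baseline)
    if (is.null(res)) {
      stop("no node scores above the baseline (", signif(baseline, 4),
           "); lower the baseline or check the score map")
    }
  } else {
    lo <- 0; hi <- max(full)
    if (hi <= 0) stop("no positively scored node; cannot build a subnetwork")
    best_gap <- Inf; res <- NULL; baseline <- NA_real_
    for (it in seq_len(20L)) {
      mid <- (lo + hi) / 2
      r <- run_at(mid)
      n_here <- if (is.null(r)) 0L else length(r$members)
      gap <- abs(n_here - target_n)
      if (!is.null(r) && (gap < best_gap ||
                          (gap == best_gap && mid > baseline))) {
        best_gap <- gap; res <- r; baseline <- mid
      }
      if (n_here == target_n) break
      if (n_here > target_n) lo <- mid else hi <- mid
    }
    if (is.null(res)) {
      stop("no admissible baseline yields a non-empty subnetwork")
    }
    if (length(res$members) != target_n) {
      warning("exact size ", target_n, " not attainable; returning ",
              length(res$members), " nodes")
    }
  }

  sub <- igraph::induced_subgraph(graph, res$members)
  structure(list(graph = sub, members = res$members, score = res$score,
                 baseline = baseline,
                 node_scores = full[res$members]),
            class = "scored_subnetwork")
}

#' @export
print.scored_subnetwork <- function(x, ...) {
  cat("scored_subnetwork: ", length(x$members), " genes, ",
      igraph::ecount(x$graph), " edges, total shifted score ",
      signif(x$score, 5), " (baseline ", signif(x$baseline, 4), ")\n",
      sep = "")
  cat(paste(utils::head(x$members, 12L), collapse = ", "),
      if (length(x$members) > 12L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' SNP-modulated gene subnetwork (full pipeline)
#'
#' Composes the three analysis steps: LD expansion of the input GWAS
#' SNPs, SNP and gene scoring, and maximum-scoring subnetwork search on
#' the interaction network. Scored genes absent from the network are
#' dropped (their count is reported via a message).
#'
#' @param snps lead-SNP data.frame (`snp`, `chrom`, `pos`, `p`).
#' @param genes gene models (`gene`, `chrom`, `start`, `end`).
#' @param network undirected [igraph::igraph] of gene interactions.
#' @param ld optional LD table (`lead`, `proxy`, `r2`).
#' @param snp_positions optional proxy position table.
#' @param p_thresh,p_floor,r2_min,window,lambda scoring parameters, see
#'   [snp_score()], [ld_expand()], [gene_scores()].
#' @param baseline,target_n see [subnetwork_search()].
#' @return a `scored_subnetwork`; its `gene_scores` attribute carries
#'   the full gene score map.
#' @export
snp_subnetwork <- function(snps, genes, network, ld = NULL,
                           snp_positions = NULL, p_thresh = 5e-8,
                           p_floor = 1e-300, r2_min = 0.8,
                           window = 50000, lambda = 2,
                           baseline = NULL, target_n = NULL) {
  expanded <- ld_expand(snps, ld, snp_positions, r2_min)
  gs <- gene_scores(expanded, genes, window, lambda, p_thresh, p_floor)
  if (length(gs) == 0L) {
    stop("no gene received a positive score; no SNP exceeds the ",
         "significance threshold near any gene")
  }
  in_net <- names(gs) %in% igraph::V(network)$name
  if (any(!in_net)) {
    message(sum(!in_net), " scored gene(s) absent from the interaction ",
            "network dropped")
  }
  gs_net <- gs[in_net]
  if (length(gs_net) == 0L) {
    stop("none of the scored genes is present in the interaction network")
  }
  res <- subnetwork_search(network, gs_net, baseline, target_n)
  attr(res, "gene_scores") <- gs
  res
}
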