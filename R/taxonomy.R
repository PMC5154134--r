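#' Assemble a cross-trait gene-score matrix
#'
#' Stacks per-trait gene score maps (as produced by [gene_scores()])
#' into one trait-by-gene matrix over the union of genes; a gene not
#' scored for a trait contributes 0. Rows and columns are sorted by
#' label, so the layout is deterministic.
#'
#' @param score_maps named list (>= 3 traits) of named numeric vectors.
#' @return numeric matrix, traits in rows, genes in columns.
#' @export
build_score_matrix <- function(score_maps) {
  if (length(score_maps) < 3L) {
    stop("need at least 3 traits to build a taxonomy (got ",
         length(score_maps), ")")
  }
  if (is.null(names(score_maps)) || anyDuplicated(names(score_maps))) {
    stop("score maps must carry unique trait names")
  }
  genes <- sort(unique(unlist(lapply(score_maps, names), use.names = FALSE)))
  traits <- sort(names(score_maps))
  m <- matrix(0, length(traits), length(genes),
              dimnames = list(traits, genes))
  for (tr in traits) {
    v <- score_maps[[tr]]
    if (any(!is.finite(v))) stop("non-finite score for trait '", tr, "'")
    m[tr, names(v)] <- unname(v)
  }
  m
}

#' Inter-trait distance from a gene-score matrix
#'
#' The distance between two traits is the cumulative difference in
#' their gene scores, i.e. the L1 (Manhattan) distance over the gene
#' union -- a genuine metric (symmetric, zero diagonal, triangle
#' inequality).
#'
#' @param m trait-by-gene score matrix from [build_score_matrix()].
#' @return a symmetric `matrix` of distances with zero diagonal.
#' @export
trait_distance <- function(m) {
  as.matrix(stats::dist(m, method = "manhattan"))
}

## clamp negative branch lengths to zero, transferring the deficit to
## the sibling edge so the sibling pair's path length is preserved
clamp_negative_branches <- function(tree) {
  for (pass in 1:2) {
    neg <- which(tree$edge.length < 0)
    for (e in neg) {
      deficit <- tree$edge.length[e]
      parent <- tree$edge[e, 1L]
      sibs <- which(tree$edge[, 1L] == parent)
      sibs <- setdiff(sibs, e)
      if (length(sibs)) {
        sib <- sibs[order(tree$edge[sibs, 2L])][1L]
        tree$edge.length[sib] <- tree$edge.length[sib] + deficit
      }
      tree$edge.length[e] <- 0
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbour-joining tree over traits
#'
#' Standard Saitou-Nei neighbour joining on an inter-trait distance
#' matrix (exact on additive distances). Negative branch lengths, which
#' NJ can produce on non-additive input, are clamped to zero with the
#' deficit transferred to a sibling edge (deterministically chosen), so
#' emitted lengths are non-negative.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 traits.
#' @return an unrooted [ape::as.phylo] tree (`phylo` object).
#' @export
trait_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(d) < 3L) stop("need at least 3 traits")
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

#' Consensus neighbour-joining taxonomy with bootstrap support
#'
#' Resamples gene columns of the score matrix with replacement `B`
#' times, rebuilding the trait distance matrix and NJ tree for each
#' replicate, and returns the majority-rule consensus topology with
#' per-edge support fractions (stored in `node.label`). Columns are
#' canonically sorted by gene label before resampling, so the result
#' depends only on the matrix content and the seed. With `B = 1` the
#' consensus is the single replicate's topology.
#'
#' @param m trait-by-gene score matrix.
#' @param B bootstrap iterations.
#' @param seed integer seed.
#' @return list of class `trait_taxonomy`: `consensus` (a `phylo` with
#'   support fractions as node labels), `tree` (the NJ tree on the full
#'   matrix), `support` (numeric vector), `B`.
#' @export
consensus_taxonomy <- function(m, B = 100, seed = 1) {
  if (ncol(m) < 1L) stop("score matrix has no gene columns")
  m <- m[sort(rownames(m)), sort(colnames(m)), drop = FALSE]
  set.seed(seed)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[b]] <- trait_tree(trait_distance(m[, cols, drop = FALSE]))
  }
  class(boots) <- "multiPhylo"
  cons <- if (B == 1L) boots[[1L]] else ape::consensus(boots, p = 0.5)
  counts <- ape::prop.clades(cons, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / B
  cons$node.label <- formatC(support, digits = 3, format = "g")
  structure(list(consensus = cons,
                 tree = trait_tree(trait_distance(m)),
                 support = support, B = B),
            class = "trait_taxonomy")
}

#' @export
print.trait_taxonomy <- function(x, ...) {
  cat("trait_taxonomy: ", length(x$consensus$tip.label), " traits, ",
      x$B, " bootstrap replicates\n", sep = "")
  cat(ape::write.tree(x$consensus), "\n")
  invisible(x)
}

#' Write a trait taxonomy as Newick plus a distance-matrix TSV
#' @param taxonomy a `trait_taxonomy` (or bare `phylo`).
#' @param newick_path output Newick file.
#' @param dist_path optional TSV for the distance matrix (requires the
#'   matrix via `distances`).
#' @param distances optional distance matrix to write.
#' @export
write_taxonomy <- function(taxonomy, newick_path, dist_path = NULL,
                           distances = NULL) {
  tree <- if (inherits(taxonomy, "trait_taxonomy")) taxonomy$consensus
          else taxonomy
  ape::write.tree(tree, file = newick_path)
  if (!is.null(dist_path) && !is.null(distances)) {
    df <- data.frame(trait = rownames(distances), distances,
                     check.names = FALSE)
    write_tsv(df, dist_path)
  }
  invisible(taxonomy)
}
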