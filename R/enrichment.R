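#' Per-term enrichment p-value for a 2x2 contingency configuration
#'
#' Tests over-representation of a term among `k` input entities drawn
#' from a background of `N`, of which `M` carry the term and `x` of the
#' input carry it. Three tests are offered:
#' \describe{
#'   \item{fisher}{one-sided Fisher's exact test: the inclusive
#'     hypergeometric upper tail `P(X >= x)`.}
#'   \item{hypergeometric}{the strict hypergeometric upper tail
#'     `P(X > x)`.}
#'   \item{binomial}{sampling with replacement at constant term
#'     frequency: `P(Bin(k, M/N) >= x)`.}
#' }
#' For enriched configurations (observed overlap exceeding expectation)
#' the resulting p-values order as hypergeometric < Fisher < binomial,
#' i.e. the hypergeometric reading is the most lenient in reporting
#' significance and the binomial the most conservative.
#'
#' All arguments are vectorised and recycled.
#'
#' @param x input entities annotated to the term.
#' @param M background entities annotated to the term.
#' @param k input entities present in the background.
#' @param N background size.
#' @param test one of `"fisher"`, `"hypergeometric"`, `"binomial"`.
#' @return numeric vector of p-values.
#' @examples
#' term_test_p(5, 5, 5, 20, "fisher")   # 1/choose(20, 5)
#' @export
term_test_p <- function(x, M, k, N,
                        test = c("fisher", "hypergeometric", "binomial")) {
  test <- match.arg(test)
  n <- max(length(x), length(M), length(k), length(N))
  x <- rep_len(x, n); M <- rep_len(M, n)
  k <- rep_len(k, n); N <- rep_len(N, n)
  if (any(M > N | k > N | x > pmin(M, k) | x < 0 | M < 0)) {
    stop("invalid contingency counts: need 0 <= x <= min(M, k), M <= N, k <= N")
  }
  switch(test,
    fisher = stats::phyper(x - 1, M, N - M, k, lower.tail = FALSE),
    hypergeometric = stats::phyper(x, M, N - M, k, lower.tail = FALSE),
    binomial = stats::pbinom(x - 1, k, M / N, lower.tail = FALSE))
}

#' Multiple-testing adjustment (FDR or FWER)
#'
#' `"fdr"` applies the Benjamini-Hochberg step-up procedure controlling
#' the false discovery rate (the default criterion throughout the
#' package); `"fwer"` applies Bonferroni, controlling the family-wise
#' error rate. FDR-adjusted values never exceed the FWER-adjusted ones
#' element-wise, FDR being the less stringent criterion.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"fdr"` or `"fwer"`.
#' @return adjusted p-values, clipped to 1, order-preserving.
#' @export
adjust_pvalues <- function(p, method = c("fdr", "fwer")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "fdr") "BH" else "bonferroni")
}

#' Ontology term enrichment of an entity list
#'
#' Tests every eligible term of an annotation set for over-representation
#' in the input, optionally respecting the ontology tree structure: in
#' tree-aware mode terms are processed leaves to root, and when a
#' descendant term has already been found significant (raw p below
#' `alpha_elim` at the elimination stage) the entities it claimed --
#' its overlap with the input -- are removed from both the overlap and
#' the annotation of every ancestor before that ancestor is tested.
#' Parents whose signal is wholly explained by a more specific child
#' term are thereby suppressed, yielding more informative results.
#'
#' @param input character vector of entity identifiers (or a data frame
#'   from [read_entity_list()], whose `id` column is used).
#' @param ann an `annotation_set` from [propagate_annotations()].
#' @param dag the [ontology_dag()] the annotations live on; required for
#'   `tree_aware = TRUE`.
#' @param background optional character vector restricting the universe;
#'   defaults to `ann$universe`.
#' @param test counting test, see [term_test_p()].
#' @param min_size,max_size bounds on a term's propagated annotation
#'   size (within background) for it to be tested.
#' @param tree_aware logical; apply the elimination procedure.
#' @param alpha_elim raw-p threshold used at the elimination stage.
#' @param adjust `"fdr"` (Benjamini-Hochberg, default) or `"fwer"`
#'   (Bonferroni).
#' @return an object of classes `eterm` and `data.frame`, one row per
#'   tested term, sorted by ascending p then term id, with columns
#'   `term_id`, `name`, `nAnno` (M), `nOverlap` (x), `fc`
#'   (observed/expected ratio), `p`, `adj_p`, `flagged_redundant`
#'   (filled by [filter_redundant()]), and a list column `members`.
#'   In tree-aware mode counts, fold changes and members reflect the
#'   post-elimination configuration.
#' @export
enrich_terms <- function(input, ann, dag = NULL, background = NULL,
                         test = c("fisher", "hypergeometric", "binomial"),
                         min_size = 10, max_size = 2000,
                         tree_aware = FALSE, alpha_elim = 0.05,
                         adjust = c("fdr", "fwer")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  stopifnot(inherits(ann, "annotation_set"))
  if (is.data.frame(input)) input <- input$id
  input <- unique(as.character(input))
  if (tree_aware && is.null(dag)) {
    stop("tree-aware enrichment requires the ontology DAG")
  }

  bg <- if (is.null(background)) ann$universe
        else intersect(unique(as.character(background)), ann$universe)
  N <- length(bg)
  if (N == 0L) stop("empty background after intersecting with the universe")
  eff <- intersect(input, bg)
  if (length(eff) == 0L) {
    stop("none of the ", length(input),
         " input entities match the annotation universe (", N, " entities)")
  }
  k <- length(eff)

  ann_bg <- lapply(ann$propagated, function(g) intersect(g, bg))
  sizes <- vapply(ann_bg, length, 1L)
  keep <- names(sizes)[sizes >= min_size & sizes <= max_size]
  if (length(keep) == 0L) {
    stop("no term has a propagated annotation size within [",
         min_size, ", ", max_size, "] in this background")
  }

  if (!tree_aware) {
    rows <- lapply(keep, function(t) {
      memb <- intersect(eff, ann_bg[[t]])
      list(term = t, M = sizes[[t]], x = length(memb), members = memb)
    })
  } else {
    ## leaves-to-root elimination: entities claimed by significant
    ## descendants are removed from ancestors before testing them
    elim <- stats::setNames(vector("list", length(keep)), keep)
    rows <- list()
    order_terms <- intersect(rev(dag$topo), keep)   # leaves first
    for (t in order_terms) {
      ann_t <- setdiff(ann_bg[[t]], elim[[t]])
      memb <- intersect(eff, ann_t)
      M <- length(ann_t); x <- length(memb)
      p_elim <- term_test_p(x, M, k, N, test)
      rows[[t]] <- list(term = t, M = M, x = x, members = memb)
      if (p_elim < alpha_elim && x > 0L) {
        anc <- setdiff(dag$ancestors[[t]], t)
        for (a in intersect(anc, keep)) {
          elim[[a]] <- unique(c(elim[[a]], memb))
        }
      }
    }
    rows <- rows[keep]
  }

  term_id <- vapply(rows, `[[`, "", "term")
  M <- vapply(rows, function(r) as.integer(r$M), 1L)
  x <- vapply(rows, function(r) as.integer(r$x), 1L)
  p <- ifelse(M == 0L, 1, term_test_p(x, M, k, N, test))
  fc <- ifelse(M > 0L, (x / k) / (M / N), NA_real_)
  nm <- if (!is.null(dag)) unname(dag$names[term_id]) else term_id
  nm[is.na(nm)] <- term_id[is.na(nm)]

  out <- data.frame(term_id = term_id, name = nm, nAnno = M, nOverlap = x,
                    fc = fc, p = p,
                    adj_p = adjust_pvalues(p, adjust),
                    flagged_redundant = FALSE,
                    stringsAsFactors = FALSE)
  out$members <- lapply(rows, function(r) sort(r$members))
  ord <- order(out$p, out$term_id)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "test") <- test
  attr(out, "n_background") <- N
  attr(out, "n_input") <- k
  attr(out, "tree_aware") <- tree_aware
  class(out) <- c("eterm", "data.frame")
  out
}

#' @export
print.eterm <- function(x, n = 10L, ...) {
  cat("eterm: ", nrow(x), " terms tested (", attr(x, "test"), " test, ",
      attr(x, "n_input"), " input entities, background ",
      attr(x, "n_background"),
      if (isTRUE(attr(x, "tree_aware"))) ", tree-aware", ")\n", sep = "")
  show <- utils::head(as.data.frame(x)[
    , c("term_id", "name", "nAnno", "nOverlap", "fc", "p", "adj_p")], n)
  print(show, digits = 4)
  if (nrow(x) > n) cat("... and ", nrow(x) - n, " more terms\n", sep = "")
  invisible(x)
}

#' Flag redundant terms among significant enrichment records
#'
#' For flat (non-structured) collections, significant terms frequently
#' restate one another. Scanning from the most significant record down,
#' a less significant term B is flagged redundant with respect to an
#' already-retained, more significant term A when both hold:
#' more than `c1` of B's input members are also members of A, and more
#' than `c2` of A's input members are also members of B. The second
#' criterion keeps small specific subsets of a broad term (different
#' knowledge granularity) from being discarded. Flagged records are not
#' used as comparators for subsequent terms.
#'
#' @param records an `eterm` object (typically filtered to significant
#'   rows) with populated `members`; must be sorted by ascending p,
#'   ties by term id (as [enrich_terms()] returns them).
#' @param c1 fraction of B covered by A required (default 0.90).
#' @param c2 fraction of A covered by B required (default 0.50).
#' @return the records with `flagged_redundant` set.
#' @export
filter_redundant <- function(records, c1 = 0.90, c2 = 0.50) {
  stopifnot(inherits(records, "eterm") || is.data.frame(records))
  records <- records[order(records$p, records$term_id), ]
  flagged <- logical(nrow(records))
  retained <- integer(0)
  for (i in seq_len(nrow(records))) {
    mb <- records$members[[i]]
    if (length(mb) == 0L) {
      warning("record '", records$term_id[[i]],
              "' has no members; skipped by the redundancy filter")
      next
    }
    for (j in retained) {
      ma <- records$members[[j]]
      ov <- length(intersect(mb, ma))
      if (ov / length(mb) > c1 && ov / length(ma) > c2) {
        flagged[i] <- TRUE
        break
      }
    }
    if (!flagged[i]) retained <- c(retained, i)
  }
  records$flagged_redundant <- flagged
  records
}

#' Write enrichment records as TSV
#'
#' Columns: term_id, name, nAnno, nOverlap, fc, p, adj_p,
#' flagged_redundant, members (comma-joined).
#' @param records an `eterm` object.
#' @param path output file.
#' @export
write_eterm <- function(records, path) {
  df <- as.data.frame(records)
  df$members <- vapply(df$members, paste, "", collapse = ",")
  write_tsv(df, path)
}

#' Export the significant sub-DAG of an enrichment result as DOT
#'
#' The significant terms plus all of their ancestors, with is_a edges,
#' in Graphviz DOT text (the plain-text counterpart of a DAG plot).
#'
#' @param records an `eterm` object.
#' @param dag the [ontology_dag()] used.
#' @param alpha adjusted-p threshold selecting significant terms.
#' @param path output file.
#' @export
eterm_dag_dot <- function(records, dag, path, alpha = 0.05) {
  sig <- records$term_id[records$adj_p < alpha]
  nodes <- sort(unique(unlist(dag$ancestors[sig], use.names = FALSE)))
  q <- function(x) paste0("\"", x, "\"")
  lines <- c("digraph enrichment {")
  for (n in nodes) {
    shape <- if (n %in% sig) " [shape=box]" else ""
    lines <- c(lines, paste0("  ", q(n), shape, ";"))
  }
  for (n in nodes) {
    for (p in intersect(dag$parents[[n]], nodes)) {
      lines <- c(lines, paste0("  ", q(n), " -> ", q(p), ";"))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
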