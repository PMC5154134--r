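#' Ontology annotation profile of an entity
#'
#' Collects the terms directly annotating an entity together with the
#' terms inherited through the true-path rule (all ancestors of the
#' direct terms). The direct set defines the profile used by the
#' best-matching similarity measures; the inherited set is retained for
#' reporting, e.g. in DOT exports of a profile.
#'
#' @param entity entity identifier.
#' @param ann an `annotation_set` from [propagate_annotations()].
#' @param dag the [ontology_dag()].
#' @return object of class `annotation_profile`: list with `entity`,
#'   `direct`, `inherited` and `terms` (= union, ancestor-closed).
#' @export
entity_profile <- function(entity, ann, dag) {
  stopifnot(inherits(ann, "annotation_set"), inherits(dag, "ontology_dag"))
  direct <- sort(names(ann$direct)[vapply(ann$direct,
                                          function(g) entity %in% g, TRUE)])
  if (length(direct) == 0L) {
    stop("entity '", entity, "' carries no direct annotation")
  }
  closed <- sort(unique(unlist(dag$ancestors[direct], use.names = FALSE)))
  structure(list(entity = entity, direct = direct,
                 inherited = setdiff(closed, direct), terms = closed),
            class = "annotation_profile")
}

#' @export
print.annotation_profile <- function(x, ...) {
  cat("annotation_profile for '", x$entity, "': ", length(x$direct),
      " direct + ", length(x$inherited), " inherited terms\n", sep = "")
  invisible(x)
}

## best-match vector: for each term in `from`, the maximal
## MICA information content against any term of `to`
best_match_ic <- function(from, to, dag, ic) {
  vapply(from, function(t1) {
    max(vapply(to, function(t2) term_mica(dag, ic, t1, t2)$ic, 1))
  }, 1)
}

#' Semantic similarity between two annotation profiles
#'
#' Pairwise term similarity is the information content of the most
#' informative common ancestor (MICA). For each directly annotating
#' term of one entity the best match (maximal MICA IC) against the
#' other entity's terms is taken; the directional best-match values are
#' combined by one of three rules:
#' \describe{
#'   \item{average}{the mean of the two directional averages.}
#'   \item{maximum}{the larger of the two directional averages.}
#'   \item{complete}{the minimum over the union of all best-match
#'     values. Adding further well-matched terms to a profile changes
#'     the average and maximum scores but never the complete score,
#'     which is why complete is the default: it minimises sensitivity
#'     to the number of annotating terms.}
#' }
#' Entities whose profiles share only the root score 0 under all three
#' rules (the root's IC is 0).
#'
#' @param p1,p2 [entity_profile()] objects.
#' @param dag the [ontology_dag()].
#' @param ic IC map from [term_ic()]. Profile terms absent from the map
#'   are dropped with a warning.
#' @param method `"complete"` (default), `"average"` or `"maximum"`.
#' @return a single non-negative similarity value; symmetric in
#'   `p1`/`p2`.
#' @export
pair_similarity <- function(p1, p2, dag, ic,
                            method = c("complete", "average", "maximum")) {
  method <- match.arg(method)
  t1 <- p1$direct; t2 <- p2$direct
  drop1 <- setdiff(t1, names(ic)); drop2 <- setdiff(t2, names(ic))
  if (length(drop1) || length(drop2)) {
    warning("term(s) missing from the IC map excluded from profiles: ",
            paste(c(drop1, drop2), collapse = ", "))
    t1 <- intersect(t1, names(ic)); t2 <- intersect(t2, names(ic))
  }
  if (length(t1) == 0L || length(t2) == 0L) {
    stop("profile empty after removing terms without information content")
  }
  bm12 <- best_match_ic(t1, t2, dag, ic)
  bm21 <- best_match_ic(t2, t1, dag, ic)
  switch(method,
    average = (mean(bm12) + mean(bm21)) / 2,
    maximum = max(mean(bm12), mean(bm21)),
    complete = min(c(bm12, bm21)))
}

#' All-pairs semantic similarity network
#'
#' Computes pairwise semantic similarity for a set of annotated
#' entities, returning a weighted undirected network (entities as
#' nodes, similarity as edge weight). Self-similarities are defined by
#' [pair_similarity()] but not emitted as edges. Optionally only the
#' `top_k` strongest edges are kept, mirroring the display of only the
#' most similar links.
#'
#' @param entities character vector (>= 2 annotated entities).
#' @param ann an `annotation_set`.
#' @param dag the [ontology_dag()].
#' @param ic optional IC map; computed from `ann` when `NULL`.
#' @param method see [pair_similarity()].
#' @param top_k optional cap on the number of edges retained (ties at
#'   the cutoff broken by entity-pair order).
#' @return object of class `similarity_network`: list with `edges`
#'   (data.frame `from`, `to`, `weight`, with `from < to`,
#'   deterministically ordered by decreasing weight then pair),
#'   `entities` and `method`.
#' @export
similarity_network <- function(entities, ann, dag, ic = NULL,
                               method = c("complete", "average", "maximum"),
                               top_k = NULL) {
  method <- match.arg(method)
  entities <- unique(as.character(entities))
  annotated <- entities[entities %in% ann$universe]
  if (length(annotated) < 2L) {
    stop("need at least 2 annotated entities (got ", length(annotated), ")")
  }
  if (is.null(ic)) ic <- term_ic(ann)
  annotated <- sort(annotated)
  profiles <- lapply(annotated, entity_profile, ann = ann, dag = dag)
  names(profiles) <- annotated

  ## cache term-term MICA IC over the union of direct terms
  terms <- sort(unique(unlist(lapply(profiles, `[[`, "direct"))))
  terms <- intersect(terms, names(ic))
  micamat <- matrix(0, length(terms), length(terms),
                    dimnames = list(terms, terms))
  for (i in seq_along(terms)) for (j in i:length(terms)) {
    v <- term_mica(dag, ic, terms[i], terms[j])$ic
    micamat[i, j] <- v; micamat[j, i] <- v
  }
  sim_cached <- function(pa, pb) {
    ta <- intersect(pa$direct, terms); tb <- intersect(pb$direct, terms)
    bm12 <- apply(micamat[ta, tb, drop = FALSE], 1L, max)
    bm21 <- apply(micamat[ta, tb, drop = FALSE], 2L, max)
    switch(method,
      average = (mean(bm12) + mean(bm21)) / 2,
      maximum = max(mean(bm12), mean(bm21)),
      complete = min(c(bm12, bm21)))
  }

  pairs <- utils::combn(annotated, 2L)
  w <- vapply(seq_len(ncol(pairs)), function(i) {
    sim_cached(profiles[[pairs[1L, i]]], profiles[[pairs[2L, i]]])
  }, 1)
  edges <- data.frame(from = pairs[1L, ], to = pairs[2L, ], weight = w,
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$from, edges$to), ]
  if (!is.null(top_k)) edges <- utils::head(edges, top_k)
  rownames(edges) <- NULL
  structure(list(edges = edges, entities = annotated, method = method),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("similarity_network: ", length(x$entities), " entities, ",
      nrow(x$edges), " edges (", x$method, " method)\n", sep = "")
  print(utils::head(x$edges, 10L), digits = 4)
  invisible(x)
}

#' Write a similarity network as edge-list and matrix TSV
#' @param net a `similarity_network`.
#' @param edge_path output path for the edge list (`from`, `to`,
#'   `weight`); `NULL` to skip.
#' @param matrix_path output path for the square similarity matrix
#'   (diagonal `NA`); `NULL` to skip.
#' @param focus optional entity id: restrict the edge list to edges
#'   touching this entity.
#' @export
write_similarity <- function(net, edge_path = NULL, matrix_path = NULL,
                             focus = NULL) {
  edges <- net$edges
  if (!is.null(focus)) {
    edges <- edges[edges$from == focus | edges$to == focus, ]
  }
  if (!is.null(edge_path)) write_tsv(edges, edge_path)
  if (!is.null(matrix_path)) {
    m <- matrix(NA_real_, length(net$entities), length(net$entities),
                dimnames = list(net$entities, net$entities))
    m[cbind(net$edges$from, net$edges$to)] <- net$edges$weight
    m[cbind(net$edges$to, net$edges$from)] <- net$edges$weight
    df <- data.frame(entity = rownames(m), m, check.names = FALSE)
    write_tsv(df, matrix_path)
  }
  invisible(net)
}
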