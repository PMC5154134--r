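#' Construct an ontology DAG from child-parent term pairs
#'
#' Builds the rooted directed acyclic graph of terms that underpins
#' annotation propagation (true-path rule), information content and
#' most-informative-common-ancestor queries. Only `is_a`-style
#' relationships are represented: each edge points from a child term to
#' one of its parents. If the supplied graph has more than one source
#' (term without parents) -- as happens for flat, non-structured term
#' collections -- an artificial root is inserted that links all sources,
#' so every ontology handled by the package is rooted.
#'
#' @param edges two-column character matrix or data.frame of
#'   (child, parent) pairs; may have zero rows.
#' @param terms character vector of all term identifiers (superset of the
#'   identifiers appearing in `edges`); isolated terms are attached to
#'   the (possibly artificial) root.
#' @param names optional named character vector mapping term identifiers
#'   to human-readable labels.
#' @param root_id identifier used when an artificial root must be
#'   created.
#'
#' @return An object of class `ontology_dag`: a list with elements
#'   `terms` (sorted identifiers), `names`, `parents` and `children`
#'   (named lists of character vectors), `root`, `topo` (a topological
#'   order from root to leaves), and `ancestors` (named list; each
#'   term's ancestor set *including itself*).
#'
#' @details A cycle among the supplied edges is a structural error: the
#'   error message names one offending edge. Self-edges are rejected.
#'
#' @examples
#' dag <- ontology_dag(rbind(c("A", "B"), c("B", "C")))
#' dag$root            # "C"
#' dag$ancestors$A     # "A" "B" "C"
#' @export
ontology_dag <- function(edges, terms = NULL, names = NULL, root_id = "ROOT") {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("`edges` must have two columns (child, parent)")
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- edges[edges[, 1L] == edges[, 2L], , drop = FALSE][1L, ]
    stop("cycle detected: self-edge ", bad[1L], " -> ", bad[2L])
  }
  edges <- unique(edges)
  all_terms <- sort(unique(c(terms, as.vector(edges))))
  if (length(all_terms) == 0L) stop("empty ontology: no terms supplied")

  parents <- split(edges[, 2L], factor(edges[, 1L], levels = all_terms))
  parents <- lapply(parents, function(p) sort(unique(p)))

  ## identify sources; insert an artificial root when there is not
  ## exactly one (flat collections and multi-rooted files)
  sources <- all_terms[vapply(parents, length, 1L) == 0L]
  if (length(sources) == 0L) {
    stop("cycle detected: no root term (every term has a parent), e.g. edge ",
         edges[1L, 1L], " -> ", edges[1L, 2L])
  }
  if (length(sources) > 1L) {
    if (root_id %in% all_terms) root_id <- paste0(root_id, ":artificial")
    edges <- rbind(edges, cbind(sources, root_id))
    all_terms <- sort(c(all_terms, root_id))
    parents <- split(edges[, 2L], factor(edges[, 1L], levels = all_terms))
    parents <- lapply(parents, function(p) sort(unique(p)))
    names <- c(names, stats::setNames("artificial root", root_id))
    root <- root_id
  } else {
    root <- sources
  }

  children <- split(edges[, 1L], factor(edges[, 2L], levels = all_terms))
  children <- lapply(children, function(p) sort(unique(p)))

  ## Kahn topological sort, root first; leftover terms witness a cycle
  indeg <- vapply(children, length, 1L)   # edges point child -> parent
  queue <- all_terms[indeg == 0L]         # leaves have indegree 0 here
  topo_rev <- character(0)
  indeg_now <- indeg
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    topo_rev <- c(topo_rev, t)
    for (p in parents[[t]]) {
      indeg_now[[p]] <- indeg_now[[p]] - 1L
      if (indeg_now[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(topo_rev) != length(all_terms)) {
    inside <- setdiff(all_terms, topo_rev)
    bad <- edges[edges[, 1L] %in% inside & edges[, 2L] %in% inside, ,
                 drop = FALSE]
    stop("cycle detected involving edge ", bad[1L, 1L], " -> ", bad[1L, 2L])
  }
  topo <- rev(topo_rev)                   # root ... leaves

  ## transitive closure of ancestry in topological order (root first),
  ## so every parent's set is complete before its children need it
  anc <- vector("list", length(all_terms))
  names(anc) <- all_terms
  for (t in topo) {
    up <- unlist(anc[parents[[t]]], use.names = FALSE)
    anc[[t]] <- sort(unique(c(t, up)))
  }

  ## every term must reach the root
  reaches <- vapply(anc, function(a) root %in% a, TRUE)
  if (!all(reaches)) {
    stop("term(s) not connected to the root: ",
         paste(utils::head(all_terms[!reaches], 5L), collapse = ", "))
  }

  lab <- stats::setNames(all_terms, all_terms)
  if (!is.null(names)) lab[names(names)] <- unname(names)

  structure(
    list(terms = all_terms, names = lab, parents = parents,
         children = children, root = root, topo = topo, ancestors = anc),
    class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, 1L))
  cat("ontology_dag: ", length(x$terms), " terms, ", n_edges,
      " is_a edges, root '", x$root, "'\n", sep = "")
  invisible(x)
}

#' Read an ontology from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, honouring `id`, `name`, `is_a` and
#' `is_obsolete` tags; obsolete terms and all other stanza types are
#' skipped. Trailing `! comment` text after an `is_a` target is
#' stripped. The result is validated and rooted by [ontology_dag()]
#' (multi-rooted files receive an artificial root).
#'
#' @param path path to an OBO file.
#' @return an [ontology_dag()] object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!any(lines == "[Term]")) {
    stop("format error in '", path, "': no [Term] stanza found")
  }
  stanza_at <- c(which(grepl("^\\[", lines)), length(lines) + 1L)
  ids <- character(0); labels <- character(0)
  edges <- matrix(character(), ncol = 2L)
  starts <- which(lines == "[Term]")
  for (s in starts) {
    e <- min(stanza_at[stanza_at > s]) - 1L
    block <- lines[seq.int(s + 1L, max(s + 1L, e))]
    field <- function(tag) {
      hit <- grep(paste0("^", tag, ":"), block, value = TRUE)
      trimws(sub(paste0("^", tag, ":"), "", hit))
    }
    id <- field("id")
    if (length(id) == 0L) next
    id <- id[1L]
    obs <- field("is_obsolete")
    if (length(obs) && tolower(obs[1L]) == "true") next
    nm <- field("name")
    isa <- field("is_a")
    isa <- trimws(sub("!.*$", "", isa))
    isa <- isa[nzchar(isa)]
    ids <- c(ids, id)
    if (length(nm)) labels <- c(labels, stats::setNames(nm[1L], id))
    if (length(isa)) edges <- rbind(edges, cbind(id, isa))
  }
  if (length(ids) == 0L) stop("format error in '", path, "': no usable terms")
  ontology_dag(edges, terms = ids, names = labels)
}

#' Propagate direct annotations up an ontology (true-path rule)
#'
#' An entity annotated to a term is implicitly annotated to every
#' ancestor of that term, so each term's propagated annotation is the
#' union of the direct annotations of all of its descendants (itself
#' included). The propagated layer is the substrate for enrichment
#' testing, information content and similarity.
#'
#' @param dag an [ontology_dag()].
#' @param direct named list mapping term identifiers to character
#'   vectors of entity identifiers.
#' @return An object of class `annotation_set`: list with `direct`
#'   (cleaned input, all terms present), `propagated`, and `universe`
#'   (all annotated entities, i.e. the root's propagated set).
#' @examples
#' dag <- ontology_dag(rbind(c("A", "B"), c("B", "C")))
#' ann <- propagate_annotations(dag, list(A = "g1"))
#' ann$propagated$C   # "g1"
#' @export
propagate_annotations <- function(dag, direct) {
  stopifnot(inherits(dag, "ontology_dag"))
  unknown <- setdiff(names(direct), dag$terms)
  if (length(unknown)) {
    stop("annotations refer to unknown term(s): ",
         paste(unknown, collapse = ", "))
  }
  dmap <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in dag$terms) dmap[[t]] <- character(0)
  for (t in names(direct)) {
    dmap[[t]] <- sort(unique(c(dmap[[t]], as.character(direct[[t]]))))
  }
  prop <- dmap
  for (t in rev(dag$topo)) {          # leaves first
    kids <- dag$children[[t]]
    if (length(kids)) {
      prop[[t]] <- sort(unique(c(prop[[t]],
                                 unlist(prop[kids], use.names = FALSE))))
    }
  }
  structure(list(direct = dmap, propagated = prop,
                 universe = prop[[dag$root]]),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  n_ann <- sum(vapply(x$direct, length, 1L) > 0L)
  cat("annotation_set: ", length(x$direct), " terms (", n_ann,
      " directly annotated), ", length(x$universe), " entities\n", sep = "")
  invisible(x)
}

#' Information content of ontology terms
#'
#' The information content (IC) of a term measures how specific it is
#' when used to annotate entities: `-log10` of the fraction of the
#' annotation universe carrying the term after true-path propagation.
#' The root, annotating everything, has IC 0; rarer terms have larger
#' IC. Terms with no propagated annotation are excluded from the map.
#'
#' @param ann an `annotation_set` from [propagate_annotations()].
#' @param universe optional explicit background of entities; defaults to
#'   `ann$universe` (all annotated entities).
#' @return named numeric vector of IC values (base-10 log units).
#' @export
term_ic <- function(ann, universe = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  if (is.null(universe)) universe <- ann$universe
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty annotation universe")
  n <- vapply(ann$propagated,
              function(g) sum(g %in% universe), 1L)
  n <- n[n > 0L]
  -log10(n / length(universe))
}

#' Most informative common ancestor of two terms
#'
#' Among the shared ancestors of `t1` and `t2` (each term counts as its
#' own ancestor), returns the one with maximal information content; ties
#' are broken by lexicographic term identifier so results are
#' deterministic. In a rooted DAG a common ancestor always exists.
#'
#' @param dag an [ontology_dag()].
#' @param ic named IC vector from [term_ic()].
#' @param t1,t2 term identifiers.
#' @return list with elements `term` and `ic`.
#' @details Equal-IC ties (frequent between a term and an ancestor
#'   annotating exactly the same entities) resolve to the most specific
#'   candidate -- the one with the largest ancestor set -- then
#'   lexicographically, so results are deterministic.
#' @export
term_mica <- function(dag, ic, t1, t2) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!t1 %in% dag$terms || !t2 %in% dag$terms) {
    stop("term(s) not in ontology: ",
         paste(setdiff(c(t1, t2), dag$terms), collapse = ", "))
  }
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  if (length(common) == 0L) stop("internal invariant failure: no common ancestor")
  vals <- ic[common]
  vals[is.na(vals)] <- 0          # unscored ancestors carry no information
  best <- max(vals)
  cand <- common[vals == best]
  depth <- vapply(dag$ancestors[cand], length, 1L)
  cand <- sort(cand[depth == max(depth)])
  list(term = cand[1L], ic = unname(best))
}

## descendants of a term (itself included); used by elimination
dag_descendants <- function(dag, term) {
  out <- character(0)
  queue <- term
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    if (t %in% out) next
    out <- c(out, t)
    queue <- c(queue, dag$children[[t]])
  }
  sort(out)
}

#' Build a rooted DAG for a flat (non-structured) term collection
#'
#' Flat collections such as pathway gene sets carry no relationships
#' between terms; an artificial root is created to link all terms so
#' the same propagation and testing machinery applies.
#'
#' @param term_ids character vector of term identifiers.
#' @param names optional named character vector of labels.
#' @return an [ontology_dag()] whose root is artificial.
#' @export
flat_ontology <- function(term_ids, names = NULL) {
  ontology_dag(matrix(character(), ncol = 2L), terms = term_ids,
               names = names)
}
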