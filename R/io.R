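#' Read a GMT file of term sets
#'
#' One set per line: name TAB description TAB member ids. Returns a
#' structure directly usable as the `direct` argument of
#' [propagate_annotations()] (together with [flat_ontology()]).
#'
#' @param path path to a GMT file.
#' @return list with `sets` (named list of member vectors) and
#'   `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error in '", path, "': empty GMT file")
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("format error in '", path, "' line ", i,
           ": need name, description and >=1 member")
    }
    sets[[f[1L]]] <- sort(unique(f[-(1:2)]))
    desc[f[1L]] <- f[2L]
  }
  list(sets = sets, descriptions = desc)
}

#' Write term sets as GMT
#' @param sets named list of member vectors.
#' @param path output file.
#' @param descriptions optional named character vector.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  nm <- sort(names(sets))
  lines <- vapply(nm, function(n) {
    d <- if (!is.null(descriptions) && n %in% names(descriptions))
      descriptions[[n]] else "na"
    paste(c(n, d, sort(unique(sets[[n]]))), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 file into a region data frame
#'
#' Coordinates are half-open and 0-based throughout the package
#' (BED-native). Malformed lines raise an error naming file and line.
#'
#' @param path path to a BED file (first three columns used).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) &
                 !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) stop("format error in '", path, "': no intervals")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad)) {
    stop("format error in '", path, "' line ", bad[1L], ": fewer than 3 fields")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("format error in '", path, "' line ",
         which(is.na(start) | is.na(end))[1L], ": non-integer coordinates")
  }
  if (any(start >= end)) {
    stop("format error in '", path, "' line ", which(start >= end)[1L],
         ": start must be < end (half-open intervals)")
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Write a region data frame as BED3 (sorted, deterministic)
#' @param regions data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(regions, path) {
  regions <- regions[order(regions$chrom, regions$start, regions$end), ]
  writeLines(paste(regions$chrom, regions$start, regions$end, sep = "\t"),
             path)
  invisible(path)
}

## strict TSV reader with required columns and file:line diagnostics
read_tsv_table <- function(path, columns, numeric_cols = character(0)) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = ""),
    error = function(e) stop("format error in '", path, "': ",
                             conditionMessage(e)))
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    stop("format error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  }
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && !anyNA(df[[cn]])) {
      stop("format error in '", path, "': non-numeric values in column ", cn)
    }
    df[[cn]] <- v
  }
  df
}

#' Read a SNP summary-statistics table (snp, chrom, pos, p)
#' @param path TSV with header columns `snp`, `chrom`, `pos`, `p`;
#'   positions are 1-based.
#' @return data.frame.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_table(path, c("snp", "chrom", "pos", "p"), c("pos", "p"))
  if (any(df$p <= 0 | df$p > 1)) {
    stop("format error in '", path, "': p-values must lie in (0, 1]")
  }
  df
}

#' Read an LD table (lead, proxy, r2)
#' @param path TSV with header columns `lead`, `proxy`, `r2`.
#' @return data.frame.
#' @export
read_ld_table <- function(path) {
  df <- read_tsv_table(path, c("lead", "proxy", "r2"), "r2")
  if (any(df$r2 < 0 | df$r2 > 1)) {
    stop("format error in '", path, "': r2 must lie in [0, 1]")
  }
  df
}

#' Read gene models (gene, chrom, start, end; half-open 0-based)
#' @param path TSV with header columns `gene`, `chrom`, `start`, `end`.
#' @return data.frame.
#' @export
read_gene_models <- function(path) {
  read_tsv_table(path, c("gene", "chrom", "start", "end"),
                 c("start", "end"))
}

#' Read a gene interaction network from an edge-list TSV
#' @param path TSV with header columns `from`, `to` and optional `weight`.
#' @return an undirected simple [igraph::igraph] object.
#' @export
read_network <- function(path) {
  df <- read_tsv_table(path, c("from", "to"))
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Export a node-scored graph in DOT format
#'
#' Plain-text graph description usable with Graphviz; node scores are
#' attached as `score` attributes, edge weights (if any) as labels.
#'
#' @param graph an [igraph::igraph] object.
#' @param path output file.
#' @param scores optional named numeric vector of node scores.
#' @export
write_dot <- function(graph, path, scores = NULL) {
  nodes <- sort(igraph::V(graph)$name)
  el <- igraph::as_edgelist(graph)
  if (nrow(el)) {
    swap <- el[, 1L] > el[, 2L]
    el[swap, ] <- el[swap, c(2L, 1L)]
    el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  }
  q <- function(x) paste0("\"", x, "\"")
  lines <- c("graph G {")
  for (n in nodes) {
    attr <- if (!is.null(scores) && n %in% names(scores))
      sprintf(" [score=%.6g]", scores[[n]]) else ""
    lines <- c(lines, paste0("  ", q(n), attr, ";"))
  }
  if (nrow(el)) {
    lines <- c(lines, paste0("  ", q(el[, 1L]), " -- ", q(el[, 2L]), ";"))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read an entity list (one id per line, optional significance column)
#' @param path text file; a second TAB-separated column, if present,
#'   is returned as `value` (ignored by enrichment itself).
#' @return data.frame with columns `id` and (possibly all-`NA`) `value`.
#' @export
read_entity_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error in '", path, "': empty list")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  id <- vapply(parts, `[[`, "", 1L)
  value <- vapply(parts, function(p)
    if (length(p) >= 2L) suppressWarnings(as.numeric(p[[2L]])) else NA_real_,
    1)
  data.frame(id = id, value = value, stringsAsFactors = FALSE)
}

## deterministic TSV writer used by the CLI
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
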