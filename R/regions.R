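## regions are plain data.frames (chrom, start, end), half-open 0-based
## (BED convention); GRanges (1-based closed) is the internal engine

regions_to_gr <- function(regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) && any(regions$start >= regions$end)) {
    stop("invalid interval: start must be < end (half-open coordinates)")
  }
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

gr_to_regions <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Merge a region set into disjoint sorted intervals
#'
#' Overlapping or bookended intervals are fused per chromosome, so
#' duplicated input can never double-count bases in downstream
#' arithmetic. All region-enrichment entry points merge their inputs.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (half-open,
#'   0-based).
#' @return merged data.frame, sorted by chrom then start.
#' @export
merge_regions <- function(regions) {
  out <- gr_to_regions(GenomicRanges::reduce(regions_to_gr(regions)))
  rownames(out) <- NULL
  out
}

#' Total bases covered by a region set (after merging)
#' @param regions region data.frame.
#' @return integer base count.
#' @export
region_bases <- function(regions) {
  m <- merge_regions(regions)
  sum(as.numeric(m$end - m$start))
}

#' Bases shared by two region sets
#'
#' Exact per-base intersection; symmetric, and additive over a
#' partition of either argument.
#'
#' @param a,b region data.frames.
#' @return numeric base count.
#' @export
overlap_bases <- function(a, b) {
  ## sets on disjoint chromosomes legitimately share no seqlevels
  ov <- suppressWarnings(
    GenomicRanges::intersect(GenomicRanges::reduce(regions_to_gr(a)),
                             GenomicRanges::reduce(regions_to_gr(b))))
  sum(as.numeric(GenomicRanges::width(ov)))
}

clip_regions <- function(regions, background) {
  gr <- GenomicRanges::reduce(regions_to_gr(regions))
  bg <- GenomicRanges::reduce(regions_to_gr(background))
  clipped <- GenomicRanges::intersect(gr, bg)
  lost <- sum(as.numeric(GenomicRanges::width(gr))) -
    sum(as.numeric(GenomicRanges::width(clipped)))
  if (lost > 0) {
    warning(lost, " input base(s) outside the background clipped")
  }
  gr_to_regions(clipped)
}

## per-chromosome cumulative-coverage lookup for an annotation track:
## cover(chrom, s, e) = annotated bases of the half-open [s, e)
coverage_index <- function(track) {
  m <- merge_regions(track)
  lapply(split(m, m$chrom), function(d) {
    bounds <- as.numeric(rbind(d$start, d$end))        # s1,e1,s2,e2,...
    cum <- cumsum(c(0, diff(bounds) *
                      rep_len(c(1, 0), length(bounds) - 1L)))
    list(bounds = bounds, cum = cum)
  })
}

covered_in <- function(idx, chrom, s, e) {
  ci <- idx[[chrom]]
  if (is.null(ci)) return(numeric(length(s)))
  at <- function(x) {
    i <- findInterval(x, ci$bounds)
    base <- ifelse(i == 0L, 0, ci$cum[pmax(i, 1L)])
    inside <- i >= 1L & i %% 2L == 1L                  # odd: inside a block
    base + ifelse(inside, x - ci$bounds[pmax(i, 1L)], 0)
  }
  at(e) - at(s)
}

#' Region-set enrichment against genomic annotation tracks
#'
#' Quantifies the co-localisation of an input region set with each of a
#' list of annotation tracks, at base resolution, relative to a
#' background. Two null models are offered:
#' \describe{
#'   \item{binomial}{each input base is a trial hitting an annotation
#'     with probability q = (annotation bases within background) /
#'     (background bases); the p-value is the binomial upper tail
#'     `P(Bin(n, q) >= observed)` with n = input bases within
#'     background.}
#'   \item{sampling}{every (merged, clipped) input interval is
#'     re-placed uniformly at random within the background `B` times,
#'     preserving its length and, where the background contains its
#'     chromosome, its chromosome; the empirical p-value is
#'     `(1 + #[null >= observed]) / (B + 1)` and a z-score against the
#'     null mean and SD is reported.}
#' }
#' P-values are Benjamini-Hochberg adjusted across tracks. The default
#' background is the union of all annotation tracks (the annotatable
#' genome); input outside the background is clipped with a warning.
#'
#' @param input region data.frame.
#' @param annotations named list of region data.frames (the tracks).
#' @param background optional region data.frame.
#' @param mode `"binomial"` or `"sampling"`.
#' @param B sampling iterations (>= 100).
#' @param seed integer seed for the sampling null.
#' @return data.frame of class `region_enrichment`: one row per track
#'   with `annotation`, `n_input_bases`, `n_annotation_bases`,
#'   `observed`, `expected`, `fc`, `p`, `adj_p`, and for the sampling
#'   mode `null_mean`, `null_sd`, `z`.
#' @export
region_enrich <- function(input, annotations, background = NULL,
                          mode = c("binomial", "sampling"), B = 2000,
                          seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    stop("annotation tracks must be named")
  }
  if (is.null(background)) {
    background <- merge_regions(do.call(rbind, annotations))
  } else {
    background <- merge_regions(background)
  }
  if (nrow(background) == 0L) stop("empty background")
  bg_bases <- region_bases(background)
  input <- clip_regions(input, background)
  if (nrow(input) == 0L) stop("no input bases remain within the background")
  n <- sum(as.numeric(input$end - input$start))

  ann_bg <- lapply(annotations, function(a) {
    gr_to_regions(GenomicRanges::intersect(
      GenomicRanges::reduce(regions_to_gr(a)), regions_to_gr(background)))
  })
  m_ann <- vapply(ann_bg, function(a)
    sum(as.numeric(a$end - a$start)), 1)
  obs <- vapply(ann_bg, function(a) overlap_bases(input, a), 1)
  q <- m_ann / bg_bases
  expected <- n * q
  fc <- ifelse(expected > 0, obs / expected, NA_real_)

  out <- data.frame(annotation = names(annotations),
                    n_input_bases = n, n_annotation_bases = m_ann,
                    observed = obs, expected = expected, fc = fc,
                    stringsAsFactors = FALSE)

  if (mode == "binomial") {
    out$p <- stats::pbinom(obs - 1, n, q, lower.tail = FALSE)
  } else {
    if (B < 100) stop("need at least 100 sampling iterations")
    if (!is.null(seed)) set.seed(seed)
    null_mat <- sample_null_overlaps(input, ann_bg, background, B)
    out$null_mean <- colMeans(null_mat)
    out$null_sd <- apply(null_mat, 2L, stats::sd)
    out$z <- ifelse(out$null_sd > 0,
                    (obs - out$null_mean) / out$null_sd, NA_real_)
    out$p <- vapply(seq_along(ann_bg), function(j) {
      (1 + sum(null_mat[, j] >= obs[[j]])) / (B + 1)
    }, 1)
  }
  out$adj_p <- adjust_pvalues(out$p, "fdr")
  ord <- order(out$p, out$annotation)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "n_background_bases") <- bg_bases
  class(out) <- c("region_enrichment", "data.frame")
  out
}

## B iterations of random re-placement; returns B x n_tracks overlaps
sample_null_overlaps <- function(input, ann_bg, background, B) {
  idx <- lapply(ann_bg, coverage_index)
  segs <- split(background, background$chrom)
  all_segs <- background
  lens <- input$end - input$start

  place <- function(len, chrom) {
    cand <- segs[[chrom]]
    if (is.null(cand)) cand <- all_segs     # chromosome absent: anywhere
    room <- cand$end - cand$start - len + 1L
    ok <- room > 0L
    if (!any(ok)) {
      stop("interval of length ", len, " on '", chrom,
           "' does not fit in any background segment")
    }
    i <- sample.int(sum(ok), 1L, prob = room[ok])
    seg <- cand[ok, , drop = FALSE][i, ]
    s <- seg$start + sample.int(seg$end - seg$start - len + 1L, 1L) - 1L
    c(s, s + len, match(seg$chrom, names(segs)))
  }

  chroms <- names(segs)
  null_mat <- matrix(0, B, length(ann_bg))
  for (b in seq_len(B)) {
    placed <- vapply(seq_len(nrow(input)), function(i)
      place(lens[[i]], input$chrom[[i]]), numeric(3))
    for (j in seq_along(ann_bg)) {
      tot <- 0
      for (ci in unique(placed[3L, ])) {
        sel <- placed[3L, ] == ci
        tot <- tot + sum(covered_in(idx[[j]], chroms[[ci]],
                                    placed[1L, sel], placed[2L, sel]))
      }
      null_mat[b, j] <- tot
    }
  }
  null_mat
}

#' @export
print.region_enrichment <- function(x, ...) {
  cat("region_enrichment (", attr(x, "mode"), " null): ", nrow(x),
      " tracks, input ", format(x$n_input_bases[1L], big.mark = ","),
      " bases, background ",
      format(attr(x, "n_background_bases"), big.mark = ","), " bases\n",
      sep = "")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Genes within a distance gap of each region
#'
#' Maps each input region to all gene models lying within `gap` bases
#' (overlap counts as distance 0) -- a window query, not a single
#' nearest neighbour, so equidistant genes are all reported. The pooled
#' unique gene set is the natural input for gene-level ontology
#' enrichment of a region list.
#'
#' @param input region data.frame (half-open, 0-based).
#' @param genes gene models (`gene`, `chrom`, `start`, `end`).
#' @param gap maximum distance in bases (>= 0; 0 keeps overlapping
#'   genes only).
#' @return list with `map` (named list: region label
#'   `chrom:start-end` -> character vector of genes) and `genes`
#'   (pooled sorted unique genes).
#' @export
nearest_genes <- function(input, genes, gap = 50000) {
  if (gap < 0) stop("gap must be non-negative")
  gr_in <- regions_to_gr(input)
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end))
  hits <- GenomicRanges::findOverlaps(gr_in, gr_gene, maxgap = gap)
  labels <- paste0(input$chrom, ":", input$start, "-", input$end)
  map <- stats::setNames(vector("list", nrow(input)), labels)
  for (i in seq_len(nrow(input))) map[[i]] <- character(0)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    map[[qh[k]]] <- c(map[[qh[k]]], genes$gene[sh[k]])
  }
  map <- lapply(map, function(g) sort(unique(g)))
  list(map = map, genes = sort(unique(unlist(map, use.names = FALSE))))
}
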