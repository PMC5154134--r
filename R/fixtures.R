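#' Generate a seeded synthetic analysis fixture
#'
#' Builds an internally consistent bundle of ontology, annotations,
#' gene models, interaction network, GWAS-like SNPs with linkage
#' blocks, and genomic region tracks, with known planted structure so
#' every analysis in the package can be exercised and checked without
#' external downloads. The bundle emulates the statistical shape of
#' real inputs -- a multi-rooted-free DAG ontology with multi-parent
#' terms, a preferential-attachment (scale-free) interaction network,
#' uniform association p-values with a handful of genome-wide
#' significant planted loci, LD proxies above and below the retention
#' threshold, and block-structured annotation tracks -- while staying
#' small enough for exhaustive oracles at the `tiny` scale.
#'
#' Everything is determined by `seed`; the caller's RNG state is
#' restored on exit.
#'
#' @param seed integer seed.
#' @param scale `"tiny"` (12 terms / 10 genes, exhaustive-oracle
#'   friendly), `"small"` (50 terms / 200 genes / 500 SNPs) or
#'   `"medium"` (200 terms / 2000 genes / 5000 SNPs).
#' @return list with components `dag`, `annotation` (an
#'   `annotation_set`), `ic`, `genes` (gene models), `network`
#'   (igraph), `snps`, `ld`, `regions` (list: `input`, `background`,
#'   `tracks`), and `truth` (planted structure: `enriched_term`,
#'   `signal_genes`, `module_genes`, `module_snps`, `enriched_track`).
#' @export
generate_fixture <- function(seed = 1,
                             scale = c("tiny", "small", "medium")) {
  scale <- match.arg(scale)
  dims <- switch(scale,
    tiny = list(terms = 12L, genes = 10L, snps = 8L, chroms = "chr1",
                spacing = 10000L, span = 1000L, tracks = 2L,
                module = 3L, signal = 4L),
    small = list(terms = 50L, genes = 200L, snps = 500L,
                 chroms = c("chr1", "chr2"), spacing = 25000L,
                 span = 2000L, tracks = 3L, module = 5L, signal = 20L),
    medium = list(terms = 200L, genes = 2000L, snps = 5000L,
                  chroms = c("chr1", "chr2", "chr3"), spacing = 25000L,
                  span = 2000L, tracks = 4L, module = 5L, signal = 50L))

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(seed)

  ## ---- ontology: random rooted DAG with occasional diamonds ----
  nt <- dims$terms
  term_ids <- sprintf("T%03d", seq_len(nt))
  edges <- NULL
  for (i in 2:nt) {
    np <- if (i > 3 && stats::runif(1) < 0.3) 2L else 1L
    pa <- sample(term_ids[seq_len(i - 1L)], min(np, i - 1L))
    edges <- rbind(edges, cbind(term_ids[i], pa))
  }
  dag <- ontology_dag(edges, terms = term_ids,
                      names = stats::setNames(
                        paste("term", seq_len(nt)), term_ids))

  ## ---- genes and genome ----
  ng <- dims$genes
  gene_ids <- sprintf("G%03d", seq_len(ng))
  per_chrom <- split(gene_ids,
                     rep(dims$chroms, length.out = ng))
  genes <- do.call(rbind, lapply(names(per_chrom), function(ch) {
    ids <- per_chrom[[ch]]
    start <- 10000L + (seq_along(ids) - 1L) * dims$spacing
    data.frame(gene = ids, chrom = ch, start = start,
               end = start + dims$span, stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene), ]
  rownames(genes) <- NULL
  chrom_len <- vapply(dims$chroms, function(ch) {
    max(genes$end[genes$chrom == ch]) + 50000L
  }, 1L)

  ## ---- annotations with one planted enriched leaf term ----
  leaves <- dag$terms[vapply(dag$children, length, 1L) == 0L]
  planted_term <- sort(leaves)[length(leaves)]
  signal_genes <- sort(sample(gene_ids, dims$signal))
  other_terms <- setdiff(dag$terms, c(dag$root, planted_term))
  direct <- stats::setNames(vector("list", length(other_terms)),
                            other_terms)
  for (g in gene_ids) {
    picks <- sample(other_terms, sample(1:3, 1L))
    for (t in picks) direct[[t]] <- c(direct[[t]], g)
  }
  direct[[planted_term]] <- signal_genes
  direct <- direct[vapply(direct, length, 1L) > 0L]
  annotation <- propagate_annotations(dag, direct)
  ic <- term_ic(annotation)

  ## ---- interaction network with a wired module ----
  net <- igraph::sample_pa(ng, power = 1, m = 2, directed = FALSE)
  igraph::V(net)$name <- gene_ids
  ## module genes: genome-adjacent on the first chromosome, wired as a
  ## path so the planted unit is connected in the network too
  ch1_genes <- genes$gene[genes$chrom == dims$chroms[1L]]
  ord <- order(genes$start[match(ch1_genes, genes$gene)])
  mid <- floor(length(ch1_genes) / 2L)
  module_genes <- ch1_genes[ord][seq.int(mid, mid + dims$module - 1L)]
  for (i in seq_len(dims$module - 1L)) {
    net <- igraph::add_edges(net, c(module_genes[i], module_genes[i + 1L]))
  }
  net <- igraph::simplify(net)

  ## ---- SNPs: uniform null p-values plus planted significant loci ----
  ns <- dims$snps
  snp_chrom <- sample(dims$chroms, ns, replace = TRUE,
                      prob = chrom_len / sum(chrom_len))
  snps <- data.frame(
    snp = sprintf("rs%04d", seq_len(ns)),
    chrom = snp_chrom,
    pos = vapply(snp_chrom, function(ch)
      sample.int(chrom_len[[ch]], 1L), 1L),
    p = stats::runif(ns), stringsAsFactors = FALSE)
  ## one genome-wide significant SNP inside each module gene span
  module_snps <- character(0)
  for (i in seq_along(module_genes)) {
    gi <- genes[genes$gene == module_genes[i], ]
    idx <- ns - length(module_genes) + i
    snps$chrom[idx] <- gi$chrom
    snps$pos[idx] <- as.integer(gi$start + round(dims$span / 2))
    snps$p[idx] <- 10^-stats::runif(1, 9.5, 12)
    module_snps <- c(module_snps, snps$snp[idx])
  }

  ## ---- LD: proxies of the planted leads, straddling the r2 cutoff ----
  ld <- NULL
  for (lead in module_snps) {
    li <- snps[snps$snp == lead, ]
    nearby <- snps$snp[snps$chrom == li$chrom &
                       abs(snps$pos - li$pos) < 40000 &
                       snps$snp != lead]
    for (pr in utils::head(nearby, 2L)) {
      ld <- rbind(ld, data.frame(lead = lead, proxy = pr,
                                 r2 = stats::runif(1, 0.5, 0.99),
                                 stringsAsFactors = FALSE))
    }
  }
  if (is.null(ld)) {
    ld <- data.frame(lead = character(0), proxy = character(0),
                     r2 = numeric(0), stringsAsFactors = FALSE)
  }

  ## ---- regions: contiguous background, block tracks, planted input ----
  background <- data.frame(chrom = dims$chroms, start = 0L,
                           end = unname(chrom_len),
                           stringsAsFactors = FALSE)
  make_track <- function(n_blocks, block_len) {
    blocks <- do.call(rbind, lapply(dims$chroms, function(ch) {
      s <- sort(sample.int(chrom_len[[ch]] - block_len, n_blocks))
      data.frame(chrom = ch, start = s, end = s + block_len,
                 stringsAsFactors = FALSE)
    }))
    merge_regions(blocks)
  }
  n_blocks <- max(3L, dims$genes %/% 20L)
  tracks <- stats::setNames(
    lapply(seq_len(dims$tracks), function(i) make_track(n_blocks, 5000L)),
    sprintf("track%d", seq_len(dims$tracks)))
  ## input: intervals planted inside track1 blocks plus random ones
  t1 <- tracks[[1L]]
  planted_rows <- t1[sample.int(nrow(t1), min(5L, nrow(t1))), ]
  planted_in <- data.frame(chrom = planted_rows$chrom,
                           start = planted_rows$start + 100L,
                           end = planted_rows$start + 600L,
                           stringsAsFactors = FALSE)
  rand_start <- vapply(seq_len(5L), function(i)
    sample.int(chrom_len[[1L]] - 600L, 1L), 1L)
  random_in <- data.frame(chrom = dims$chroms[1L], start = rand_start,
                          end = rand_start + 500L,
                          stringsAsFactors = FALSE)
  input_regions <- merge_regions(rbind(planted_in, random_in))

  list(dag = dag, annotation = annotation, ic = ic, genes = genes,
       network = net, snps = snps, ld = ld,
       regions = list(input = input_regions, background = background,
                      tracks = tracks),
       truth = list(enriched_term = planted_term,
                    signal_genes = signal_genes,
                    module_genes = module_genes,
                    module_snps = module_snps,
                    enriched_track = names(tracks)[1L]),
       scale = scale, seed = seed)
}

#' Write a fixture bundle to plain-text files
#'
#' Emits every component in its interchange format (OBO-like term
#' table as GMT + TSVs, BED tracks, SNP/LD/gene/network TSVs) inside
#' `dir`; file content is deterministic given the fixture.
#'
#' @param fx a fixture from [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  ## ontology as an OBO 1.2 subset
  lines <- c("format-version: 1.2", "")
  for (t in fx$dag$terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t),
               paste0("name: ", fx$dag$names[[t]]),
               paste0("is_a: ", fx$dag$parents[[t]]), "")
  }
  writeLines(lines, fp("ontology.obo"))
  direct <- fx$annotation$direct
  write_gmt(direct[vapply(direct, length, 1L) > 0L], fp("annotations.gmt"))
  write_tsv(fx$genes, fp("genes.tsv"))
  write_tsv(fx$snps, fp("snps.tsv"))
  write_tsv(fx$ld, fp("ld.tsv"))
  el <- igraph::as_edgelist(fx$network)
  write_tsv(data.frame(from = el[, 1L], to = el[, 2L]), fp("network.tsv"))
  write_bed(fx$regions$input, fp("input_regions.bed"))
  write_bed(fx$regions$background, fp("background.bed"))
  for (nm in names(fx$regions$tracks)) {
    write_bed(fx$regions$tracks[[nm]], fp(paste0(nm, ".bed")))
  }
  invisible(dir)
}
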