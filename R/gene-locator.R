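#' Locate the top match of a gene in an assembled genome
#'
#' Seed-and-extend search: the gene's k-mers are matched on both strands of
#' the genome, colinear anchors are chained, and inter-anchor intervals are
#' compared gap-free to estimate identity.  Hits are ranked by
#' `identity * query_coverage` ("highest similarity and coverage"), ties
#' broken by identity, then (chromosome, start), so the top match is
#' deterministic.
#'
#' @param gene a length-1 named [Biostrings::DNAStringSet] or a character
#'   string (then `gene_id` must be given).
#' @param genome a named [Biostrings::DNAStringSet], FASTA path, or a
#'   prebuilt `kmer_index` of the genome.
#' @param gene_id identifier used in the output when `gene` is a string.
#' @param min_coverage,min_identity hits below either threshold are
#'   discarded; if none remain the gene is reported as absent (`NULL`).
#' @param k seed size used if `genome` is not already an index.
#' @return a one-row data.frame
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`, `identity`,
#'   `query_coverage`, `score`), or `NULL` if no acceptable hit.
#' @export
top_match <- function(gene, genome, gene_id = NULL,
                      min_coverage = 0.5, min_identity = 0.8, k = 15L) {
  hits <- gene_hits(gene, genome, gene_id = gene_id, k = k)
  hits <- hits[hits$identity >= min_identity &
               hits$query_coverage >= min_coverage, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits[1L, , drop = FALSE]
}

#' All candidate hits of a gene, ranked
#'
#' @inheritParams top_match
#' @return a data.frame of hits sorted best-first (possibly 0 rows).
#' @export
gene_hits <- function(gene, genome, gene_id = NULL, k = 15L) {
  if (methods::is(gene, "DNAStringSet")) {
    gene_id <- names(gene)[1L]
    gene <- as.character(gene[[1L]])
  }
  if (is.null(gene_id)) stop("gene id required", call. = FALSE)
  index <- if (inherits(genome, "kmer_index")) genome
           else index_reference(genome, k = k)
  if (nchar(gene) < index$k)
    stop("gene shorter than seed size", call. = FALSE)
  cand <- candidate_placements(gene_id, gene, index,
                               min_chain_bases = index$k)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      query_coverage = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  L <- nchar(gene)
  out <- data.frame(
    gene_id = cand$scf_id, chrom = cand$ref_chrom,
    start = cand$ref_start, end = cand$ref_end, strand = cand$strand,
    identity = cand$identity,
    query_coverage = pmin(1, (cand$scf_end - cand$scf_start + 1) / L),
    stringsAsFactors = FALSE
  )
  out$score <- out$identity * out$query_coverage
  out[order(-out$score, -out$identity, out$chrom, out$start), , drop = FALSE]
}

#' Locate several genes and tabulate their top matches
#'
#' @param genes multi-FASTA path or named [Biostrings::DNAStringSet].
#' @param genome genome FASTA/DNAStringSet or `kmer_index`.
#' @param ... passed to [top_match()].
#' @return data.frame with one row per gene; genes with no acceptable hit
#'   get NA coordinates.
#' @export
locate_genes <- function(genes, genome, ...) {
  genes <- as_genome(genes)
  if (!inherits(genome, "kmer_index")) genome <- index_reference(genome)
  rows <- lapply(seq_along(genes), function(i) {
    h <- top_match(as.character(genes[[i]]), genome,
                   gene_id = names(genes)[i], ...)
    if (is.null(h))
      h <- data.frame(gene_id = names(genes)[i], chrom = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, identity = NA_real_,
                      query_coverage = NA_real_, score = NA_real_,
                      stringsAsFactors = FALSE)
    h
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Physical distance between two gene hits
#'
#' The outer span from the upstream gene's start to the downstream gene's
#' end: `max(end) - min(start)`.  This is the convention that reproduces
#' published inter-gene distances computed from top-match coordinates.
#'
#' @param hit1,hit2 one-row data.frames with `chrom`, `start`, `end`
#'   (e.g. from [top_match()]).
#' @return a list with `bp` (integer span) and `kb` (one decimal, half-up).
#' @export
gene_distance <- function(hit1, hit2) {
  if (hit1$chrom != hit2$chrom)
    stop(sprintf("different chromosomes: %s vs %s", hit1$chrom, hit2$chrom),
         call. = FALSE)
  bp <- max(hit1$end, hit2$end) - min(hit1$start, hit2$start)
  list(bp = bp, kb = round_half_up(bp / 1000, 1))
}
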