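#' N50 of a set of scaffold lengths
#'
#' The smallest length L such that scaffolds of length >= L together contain
#' at least half of the total assembled bases (descending cumulative-sum
#' convention).
#'
#' @param lengths numeric vector of scaffold lengths, all positive.
#' @return the N50 length (always one of `lengths`).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length set", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= sum(s) / 2)[1L]]
}

#' Total sequenced bases from read count and read length
#'
#' @param n_reads number of reads.
#' @param read_len read length in bp.
#' @return total base pairs (numeric, exact for counts beyond integer range).
#' @export
total_read_bp <- function(n_reads, read_len) {
  as.numeric(n_reads) * as.numeric(read_len)
}

#' Summarize an assembly
#'
#' Scaffold-level statistics (count, total length, mean, longest, N50) plus,
#' when a build is supplied, the assembled genome size and its coverage of
#' each reference.
#'
#' @param scaffolds named [Biostrings::DNAStringSet] or FASTA path.
#' @param build optional `assembly_build` from [build_pseudomolecules()].
#' @param reference_sizes optional named numeric vector of reference genome
#'   sizes (bp) for coverage percentages.
#' @return a list of class `asm_stats` with fields `n_scaffolds`, `total_bp`,
#'   `mean_len`, `max_len`, `n50`, and when available `genome_size` and
#'   `coverage_pct` (named vector, one decimal).
#' @export
assembly_stats <- function(scaffolds, build = NULL, reference_sizes = NULL) {
  scaffolds <- as_genome(scaffolds)
  lens <- Biostrings::width(scaffolds)
  out <- list(
    n_scaffolds = length(lens),
    total_bp = sum(as.numeric(lens)),
    mean_len = sum(as.numeric(lens)) / length(lens),
    max_len = max(lens),
    n50 = n50(lens)
  )
  if (!is.null(build)) out$genome_size <- build$genome_size
  if (!is.null(reference_sizes) && !is.null(out$genome_size)) {
    out$coverage_pct <- vapply(reference_sizes, function(rs)
      coverage_percent(out$genome_size, rs), numeric(1))
  }
  class(out) <- "asm_stats"
  out
}

#' @export
print.asm_stats <- function(x, ...) {
  cat("Assembly summary\n")
  cat(sprintf("  scaffolds:   %d\n", x$n_scaffolds))
  cat(sprintf("  total bp:    %s\n", format(x$total_bp, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  mean length: %s bp\n",
              format(round_half_up(x$mean_len), big.mark = ",")))
  cat(sprintf("  longest:     %s bp\n", format(x$max_len, big.mark = ",")))
  cat(sprintf("  N50:         %s bp\n", format(x$n50, big.mark = ",")))
  if (!is.null(x$genome_size))
    cat(sprintf("  genome size: %s bp\n",
                format(x$genome_size, big.mark = ",", scientific = FALSE)))
  if (!is.null(x$coverage_pct))
    for (nm in names(x$coverage_pct))
      cat(sprintf("  coverage of %s: %.1f%%\n", nm, x$coverage_pct[[nm]]))
  invisible(x)
}

#' Write an assembly stats report as TSV
#' @param stats an `asm_stats` object.
#' @param path output path.
#' @export
write_stats <- function(stats, path) {
  kv <- data.frame(
    stat = c("n_scaffolds", "total_bp", "mean_len", "max_len", "n50",
             if (!is.null(stats$genome_size)) "genome_size",
             if (!is.null(stats$coverage_pct))
               paste0("coverage_pct_", names(stats$coverage_pct))),
    value = c(stats$n_scaffolds, stats$total_bp, stats$mean_len,
              stats$max_len, stats$n50, stats$genome_size,
              unname(stats$coverage_pct)),
    stringsAsFactors = FALSE
  )
  utils::write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
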