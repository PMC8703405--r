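#' @importFrom data.table data.table setkey setkeyv := .N .SD rbindlist setorder as.data.table
#' @import Biostrings
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "kmer", "chrom", "pos", "ref_start", "scf_start", "diag", "grp", "len",
  "ref_chrom", "strand", "n_occ", ".", "class_", "index", "dominant",
  "qual", "off", "pa", "pb", "start", "end", "origin", "scf_id"
))

#' Round half up
#'
#' Base `round()` rounds half to even; assembly and composition tables in
#' this package report percentages with conventional half-up rounding.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return `x` rounded half-up to `digits` decimals
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Reverse complement of a character sequence
#' @param x character vector of DNA strings
#' @return reverse-complemented strings
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# stopifnot-style scalar checks used across modules
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# read a named DNAStringSet, uppercased, from a FASTA path or pass through
as_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (!methods::is(x, "DNAStringSet"))
    stop("expected a DNAStringSet or a FASTA file path", call. = FALSE)
  if (length(x) > 0L && (is.null(names(x)) || anyNA(names(x))))
    stop("sequences must be named", call. = FALSE)
  # keep only the first word of FASTA headers, as aligners do
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @importFrom methods is
NULL
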