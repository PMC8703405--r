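# Independent oracles used across test files.  These deliberately use the
# most direct formulation of each definition (enumeration, cumulative sums)
# rather than the package's algorithms.

# N50 straight from the definition: the largest scaffold length L such that
# scaffolds of length >= L together contain at least half the total bases
# (equivalently, the length at which the descending cumulative sum first
# crosses one half).
n50_bruteforce <- function(lengths) {
  half <- sum(lengths) / 2
  cand <- unique(lengths)
  ok <- vapply(cand, function(L) sum(lengths[lengths >= L]) >= half,
               logical(1))
  max(cand[ok])
}

# exhaustive colinear chaining: maximum over all subsets of anchors that are
# strictly increasing in both coordinates with junction gaps <= max_gap,
# scored as overlap-trimmed bases minus the diagonal-shift penalty.
chain_bruteforce <- function(anchors, max_gap = 10000) {
  n <- nrow(anchors)
  stopifnot(n <= 12)
  r <- anchors$ref_start; q <- anchors$scf_start; l <- anchors$len
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sel <- sel[order(r[sel], q[sel])]
    ok <- TRUE; score <- l[sel[1]]
    if (length(sel) > 1) {
      for (t in 2:length(sel)) {
        i <- sel[t - 1]; j <- sel[t]
        if (r[j] <= r[i] || q[j] <= q[i]) { ok <- FALSE; break }
        g_r <- r[j] - (r[i] + l[i]); g_q <- q[j] - (q[i] + l[i])
        if (g_r > max_gap || g_q > max_gap) { ok <- FALSE; break }
        gained <- max(0, l[j] - max(0, -min(g_r, g_q)))
        score <- score + gained - abs(g_r - g_q)
      }
    }
    if (ok && score > best) best <- score
  }
  best
}

# random anchor instance on one chromosome/strand
random_anchors <- function(n, seed, span = 5000) {
  set.seed(seed)
  data.frame(
    ref_chrom = "chrT",
    ref_start = sort(sample.int(span, n)),
    scf_start = sample.int(span, n),
    len = sample(15:60, n, replace = TRUE)
  )
}

# base-pair fraction of each origin in a truth segment table
truth_bp_fracs <- function(truth) {
  bp <- tapply(truth$end - truth$start + 1, truth$origin, sum)
  fr <- as.numeric(bp) / sum(bp)
  names(fr) <- names(bp)
  fr
}

# origin of the segment containing position pos on chrom
truth_origin_at <- function(truth, chrom, pos) {
  row <- truth[truth$chrom == chrom & truth$start <= pos & truth$end >= pos, ]
  if (nrow(row) == 0) NA_character_ else row$origin[1]
}

# a tiny deterministic genome for hand-built cases
toy_genome <- function(len = 5000, seed = 42, name = "chrT") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  Biostrings::DNAStringSet(stats::setNames(s, name))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

mutate_seq <- function(s, n_sub, seed) {
  set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  where <- sample.int(length(ch), n_sub)
  ch[where] <- vapply(ch[where],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(ch, collapse = "")
}
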