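#' Build a k-mer position index of a reference genome
#'
#' Maps every non-ambiguous k-mer of the reference to its occurrence
#' positions.  K-mers occurring more than `max_occ` times are treated as
#' repetitive and masked (dropped from the index), so seeding never anchors
#' inside high-copy repeats.
#'
#' @param reference a named [Biostrings::DNAStringSet] or FASTA path.
#' @param k k-mer size; 15 resolves sub-megabase genomes uniquely.
#' @param max_occ occurrence threshold above which a k-mer is masked.
#' @return an object of class `kmer_index`: a list with the keyed
#'   [data.table::data.table] of (kmer, chrom, pos), `k`, and the reference
#'   sequences and lengths.
#' @export
index_reference <- function(reference, k = 15L, max_occ = 50L) {
  reference <- as_genome(reference)
  if (length(reference) == 0L || sum(Biostrings::width(reference)) == 0L)
    stop("reference is empty", call. = FALSE)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  seqs <- toupper(as.character(reference))
  tabs <- vector("list", length(seqs))
  for (ci in seq_along(seqs)) {
    L <- nchar(seqs[ci])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    km <- substring(seqs[ci], starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", km)
    tabs[[ci]] <- data.table(kmer = km[ok], chrom = names(seqs)[ci],
                             pos = starts[ok])
  }
  dt <- rbindlist(tabs)
  if (nrow(dt) == 0L) stop("reference has no indexable k-mers", call. = FALSE)
  dt[, n_occ := .N, by = kmer]
  dt <- dt[n_occ <= max_occ][, n_occ := NULL]  # repetitive k-mers masked
  # a fully repetitive reference leaves an empty (but valid) index
  setkey(dt, kmer)
  structure(list(table = dt, k = k, max_occ = as.integer(max_occ),
                 sequences = seqs,
                 lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = "kmer_index")
}

# exact k-mer anchors of a query sequence against the index, one strand.
# Returns data.table(ref_chrom, ref_start, scf_start, len) with len = k.
seed_anchors <- function(query_seq, index) {
  k <- index$k
  L <- nchar(query_seq)
  if (L < k) return(data.table())
  starts <- seq_len(L - k + 1L)
  km <- substring(query_seq, starts, starts + k - 1L)
  q <- data.table(kmer = km, scf_start = starts)
  hits <- index$table[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(data.table())
  data.table(ref_chrom = hits$chrom, ref_start = hits$pos,
             scf_start = hits$scf_start, len = index$k)
}

# collapse anchors that are consecutive on the same diagonal into maximal
# runs, so error-free stretches become a single long anchor before chaining.
collapse_anchors <- function(anchors) {
  if (nrow(anchors) == 0L) return(anchors)
  a <- data.table::copy(anchors)
  a[, diag := ref_start - scf_start]
  setorder(a, ref_chrom, diag, ref_start)
  a[, grp := cumsum(c(1L, diff(ref_start) != 1L)), by = .(ref_chrom, diag)]
  runs <- a[, .(ref_start = ref_start[1L], scf_start = scf_start[1L],
                len = ref_start[.N] - ref_start[1L] + len[.N]),
            by = .(ref_chrom, diag, grp)]
  runs[, c("diag", "grp") := NULL]
  setorder(runs, ref_chrom, ref_start, scf_start)
  runs[]
}

# score of joining anchor j after anchor i (or NA if incompatible):
# gained bases = anchor length minus any overlap with the previous anchor,
# penalty = diagonal shift (implied indel length).
chain_gain <- function(r_i, q_i, l_i, r_j, q_j, l_j, max_gap) {
  if (r_j <= r_i || q_j <= q_i) return(NA_real_)
  g_r <- r_j - (r_i + l_i)
  g_q <- q_j - (q_i + l_i)
  if (g_r > max_gap || g_q > max_gap) return(NA_real_)
  ov <- max(0, -min(g_r, g_q))
  max(0, l_j - ov) - abs(g_r - g_q)
}

#' Chain colinear anchors
#'
#' Weighted longest-increasing-subsequence chaining over anchors of one
#' (chromosome, strand) group: the chain score is the sum of overlap-trimmed
#' anchor bases minus, for each junction, the absolute difference between
#' the reference gap and the query gap (the implied indel length).
#' Junction gaps larger than `max_gap` on either coordinate are forbidden.
#' Chains are extracted best-first; anchors already used are not reused, and
#' extraction stops below `min_chain_bases`.
#'
#' @param anchors a data.frame/data.table with columns `ref_chrom`,
#'   `ref_start`, `scf_start`, `len`, all one chromosome and strand,
#'   sorted by `ref_start`.
#' @param max_gap maximum junction gap on either coordinate (bp).
#' @param min_chain_bases minimum chain score to report.
#' @param max_chains cap on the number of chains returned.
#' @return a list of chains; each chain is a list with `anchors` (the member
#'   rows, in order), `score`, `anchored_bases`.
#' @export
chain_anchors <- function(anchors, max_gap = 10000L, min_chain_bases = 100L,
                          max_chains = 20L) {
  a <- as.data.table(anchors)
  if (nrow(a) == 0L) return(list())
  setorder(a, ref_start, scf_start)
  n <- nrow(a)
  r <- a$ref_start; q <- a$scf_start; l <- as.numeric(a$len)
  alive <- rep(TRUE, n)
  chains <- list()
  while (sum(alive) > 0L && length(chains) < max_chains) {
    idx <- which(alive)
    m <- length(idx)
    dp <- l[idx]
    back <- rep(0L, m)
    if (m > 1L) {
      for (jj in 2L:m) {
        j <- idx[jj]
        for (ii in seq_len(jj - 1L)) {
          i <- idx[ii]
          g <- chain_gain(r[i], q[i], l[i], r[j], q[j], l[j], max_gap)
          if (!is.na(g) && dp[ii] + g > dp[jj]) {
            dp[jj] <- dp[ii] + g
            back[jj] <- ii
          }
        }
      }
    }
    best <- which.max(dp)
    if (dp[best] < min_chain_bases) break
    path <- integer()
    cur <- best
    while (cur != 0L) { path <- c(cur, path); cur <- back[cur] }
    members <- idx[path]
    # anchored bases = overlap-trimmed coverage along the chain
    ab <- l[members[1L]]
    if (length(members) > 1L) {
      for (t in 2L:length(members)) {
        i <- members[t - 1L]; j <- members[t]
        g_r <- r[j] - (r[i] + l[i]); g_q <- q[j] - (q[i] + l[i])
        ab <- ab + max(0, l[j] - max(0, -min(g_r, g_q)))
      }
    }
    chains[[length(chains) + 1L]] <- list(
      anchors = a[members], score = dp[best], anchored_bases = ab
    )
    alive[members] <- FALSE
  }
  chains
}

# identity of a chain over its projected placement interval: anchored
# columns are exact; equal-length inter-anchor (and end-extension) intervals
# are compared column-wise; unequal intervals additionally contribute their
# length difference as mismatches.
chain_identity <- function(chain_anchors_dt, ref_seq, query_seq,
                           pl_ref_start, pl_ref_end, pl_scf_start, pl_scf_end) {
  a <- chain_anchors_dt
  span <- pl_ref_end - pl_ref_start + 1L
  mism <- 0
  count_mismatch <- function(r1, r2, q1, q2) {
    lr <- r2 - r1 + 1L; lq <- q2 - q1 + 1L
    if (lr <= 0L && lq <= 0L) return(0)
    m <- abs(lr - lq)
    cmp <- min(lr, lq)
    if (cmp > 0L) {
      x <- strsplit(substr(ref_seq, r1, r1 + cmp - 1L), "", fixed = TRUE)[[1]]
      y <- strsplit(substr(query_seq, q1, q1 + cmp - 1L), "", fixed = TRUE)[[1]]
      m <- m + sum(x != y)
    }
    m
  }
  # left extension before the first anchor
  mism <- mism + count_mismatch(pl_ref_start, a$ref_start[1L] - 1L,
                                pl_scf_start, a$scf_start[1L] - 1L)
  if (nrow(a) > 1L) {
    for (t in 2L:nrow(a)) {
      mism <- mism + count_mismatch(
        a$ref_start[t - 1L] + a$len[t - 1L], a$ref_start[t] - 1L,
        a$scf_start[t - 1L] + a$len[t - 1L], a$scf_start[t] - 1L
      )
    }
  }
  nlast <- nrow(a)
  mism <- mism + count_mismatch(a$ref_start[nlast] + a$len[nlast], pl_ref_end,
                                a$scf_start[nlast] + a$len[nlast], pl_scf_end)
  max(0, 1 - mism / span)
}

# all candidate placements of one query sequence: seeds both strands,
# chains per (chromosome, strand), evaluates identity over the projected
# full-query interval.  Coordinates reported in the forward query frame.
candidate_placements <- function(id, query_seq, index, max_gap = 10000L,
                                 min_chain_bases = 100L, max_chains = 20L) {
  query_seq <- toupper(query_seq)
  L <- nchar(query_seq)
  out <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") query_seq else revcomp(query_seq)
    anchors <- seed_anchors(qseq, index)
    if (nrow(anchors) == 0L) next
    for (chr in unique(anchors$ref_chrom)) {
      runs <- collapse_anchors(anchors[ref_chrom == chr])
      chains <- chain_anchors(runs, max_gap = max_gap,
                              min_chain_bases = min_chain_bases,
                              max_chains = max_chains)
      for (ch in chains) {
        a <- ch$anchors
        nlast <- nrow(a)
        c_r1 <- a$ref_start[1L]
        c_r2 <- a$ref_start[nlast] + a$len[nlast] - 1L
        c_q1 <- a$scf_start[1L]
        c_q2 <- a$scf_start[nlast] + a$len[nlast] - 1L
        # project the full query onto the reference, clipped at chrom ends
        ref_len <- index$lengths[[chr]]
        ext_l <- min(c_q1 - 1L, c_r1 - 1L)
        ext_r <- min(L - c_q2, ref_len - c_r2)
        p_r1 <- c_r1 - ext_l; p_r2 <- c_r2 + ext_r
        p_q1 <- c_q1 - ext_l; p_q2 <- c_q2 + ext_r
        ident <- chain_identity(a, index$sequences[[chr]], qseq,
                                p_r1, p_r2, p_q1, p_q2)
        # report query coordinates in the forward frame
        if (strand == "+") {
          f_q1 <- p_q1; f_q2 <- p_q2
        } else {
          f_q1 <- L - p_q2 + 1L; f_q2 <- L - p_q1 + 1L
        }
        out[[length(out) + 1L]] <- data.table(
          ref_chrom = chr, ref_start = p_r1, ref_end = p_r2,
          scf_id = id, scf_start = f_q1, scf_end = f_q2, strand = strand,
          anchored_bases = ch$anchored_bases,
          identity = ident,
          score = ch$anchored_bases * ident,
          chain_score = ch$score
        )
      }
    }
  }
  if (length(out) == 0L) return(data.table())
  rbindlist(out)
}

#' Place one scaffold on the reference
#'
#' Seeds the scaffold's k-mers on both strands, chains colinear anchors per
#' (chromosome, strand), and keeps the single best chain, scored as
#' anchored bases times identity.  The reported interval is the projection
#' of the whole scaffold.  Ties are broken by (lower chromosome name, lower
#' reference start) so output is deterministic.
#'
#' @param scaffold a length-1 named [Biostrings::DNAStringSet], or a single
#'   character string (then `id` must be given).
#' @param index a [index_reference()] result.
#' @param id scaffold identifier when `scaffold` is a bare string.
#' @param max_gap,min_chain_bases chaining parameters, see [chain_anchors()].
#' @return a one-row data.frame placement
#'   (`ref_chrom`, `ref_start`, `ref_end`, `scf_id`, `scf_start`, `scf_end`,
#'   `strand`, `anchored_bases`, `identity`, `score`), or `NULL` when the
#'   scaffold is unplaced.
#' @export
place_scaffold <- function(scaffold, index, id = NULL, max_gap = 10000L,
                           min_chain_bases = 100L) {
  if (methods::is(scaffold, "DNAStringSet")) {
    id <- names(scaffold)[1L]
    scaffold <- as.character(scaffold[[1L]])
  }
  if (is.null(id)) stop("scaffold id required", call. = FALSE)
  cand <- candidate_placements(id, scaffold, index, max_gap = max_gap,
                               min_chain_bases = min_chain_bases)
  if (nrow(cand) == 0L) return(NULL)
  setorder(cand, -score, ref_chrom, ref_start)
  best <- cand[1L]
  best[, chain_score := NULL]
  as.data.frame(best)
}

#' Place a set of scaffolds on the reference
#'
#' @param scaffolds a named [Biostrings::DNAStringSet] or FASTA path.
#' @param index a [index_reference()] result.
#' @param ... passed to [place_scaffold()].
#' @return a data.frame of placements (one row per placed scaffold) with an
#'   attribute `unplaced` listing the ids of unplaced scaffolds.
#' @export
place_scaffolds <- function(scaffolds, index, ...) {
  scaffolds <- as_genome(scaffolds)
  rows <- vector("list", length(scaffolds))
  seqs <- as.character(scaffolds)
  for (i in seq_along(seqs))
    rows[[i]] <- place_scaffold(seqs[[i]], index, id = names(seqs)[i], ...)
  placed <- rbindlist(rows)
  unplaced <- setdiff(names(scaffolds), placed$scf_id)
  out <- as.data.frame(placed)
  attr(out, "unplaced") <- unplaced
  out
}

#' Write placements as a coords-style TSV
#'
#' Columns mirror MUMmer's show-coords semantics: 1-based inclusive
#' intervals on both reference and scaffold.
#'
#' @param placements data.frame from [place_scaffolds()].
#' @param path output path.
#' @export
write_placements <- function(placements, path) {
  utils::write.table(placements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a placements TSV written by [write_placements()]
#' @param path input path.
#' @return a data.frame of placements.
#' @export
read_placements <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
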