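#' Simulation configuration for a synthetic introgression trio
#'
#' Describes the synthetic study system: two named founder genomes (the
#' recurrent parent "A" and the donor parent "B"), a third, more diverged
#' "unknown" founder "U", and an offspring whose genome is a segment-wise
#' mosaic of the three.  All lengths are in bp and coordinates are 1-based
#' inclusive.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len length of each chromosome (bp).
#' @param snp_rate per-bp probability that a position segregates among the
#'   three founders (biallelic sites).
#' @param target_fracs numeric length-3 vector `(A, B, U)` of segment-origin
#'   probabilities; must sum to 1.
#' @param mean_segment_len mean mosaic segment length (bp); segment lengths
#'   are `min_segment_len` plus an exponential with the remaining mean.
#' @param min_segment_len hard lower bound on segment length (bp).
#' @param scaffold_len_mean,scaffold_len_sd arithmetic mean and sd of the
#'   lognormal scaffold length distribution (bp).
#' @param scaffold_error_rate per-bp substitution error rate applied to
#'   emitted scaffolds.
#' @param n_genes number of marker genes sampled from the offspring genome.
#' @param gene_len length of each marker gene (bp).
#' @param private_fracs length-3 vector: proportion of segregating sites
#'   private to founder A, B and U respectively.  The default gives the
#'   unknown founder half of all private alleles, i.e. it is more diverged
#'   from either parent than the parents are from each other.
#' @param qual_default constant QUAL written to VCF records.
#' @param qual_low,qual_low_frac a fraction `qual_low_frac` of sites is
#'   written with QUAL `qual_low` instead, to exercise quality filters.
#' @param seed integer seed driving all randomness.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chrom = 10L,
                       chrom_len = 500000L,
                       snp_rate = 1 / 200,
                       target_fracs = c(0.61, 0.23, 0.16),
                       mean_segment_len = 200000,
                       min_segment_len = 100000,
                       scaffold_len_mean = 25000,
                       scaffold_len_sd = 15000,
                       scaffold_error_rate = 0.001,
                       n_genes = 5L,
                       gene_len = 1500L,
                       private_fracs = c(0.25, 0.25, 0.5),
                       qual_default = 60,
                       qual_low = 10,
                       qual_low_frac = 0,
                       seed = 1L) {
  cfg <- list(
    n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
    snp_rate = snp_rate, target_fracs = as.numeric(target_fracs),
    mean_segment_len = mean_segment_len, min_segment_len = min_segment_len,
    scaffold_len_mean = scaffold_len_mean, scaffold_len_sd = scaffold_len_sd,
    scaffold_error_rate = scaffold_error_rate,
    n_genes = as.integer(n_genes), gene_len = as.integer(gene_len),
    private_fracs = as.numeric(private_fracs),
    qual_default = qual_default, qual_low = qual_low,
    qual_low_frac = qual_low_frac, seed = as.integer(seed)
  )
  assert_scalar_num(cfg$n_chrom, "n_chrom", 1)
  assert_scalar_num(cfg$chrom_len, "chrom_len", 1)
  assert_scalar_num(cfg$snp_rate, "snp_rate", 0, 1 - 1e-12)
  assert_scalar_num(cfg$scaffold_error_rate, "scaffold_error_rate", 0, 1 - 1e-12)
  assert_scalar_num(cfg$qual_low_frac, "qual_low_frac", 0, 1)
  if (length(cfg$target_fracs) != 3L || any(cfg$target_fracs < 0) ||
      abs(sum(cfg$target_fracs) - 1) > 1e-9)
    stop("target_fracs must be three non-negative numbers summing to 1",
         call. = FALSE)
  if (length(cfg$private_fracs) != 3L || any(cfg$private_fracs < 0) ||
      abs(sum(cfg$private_fracs) - 1) > 1e-9)
    stop("private_fracs must be three non-negative numbers summing to 1",
         call. = FALSE)
  for (f in c("mean_segment_len", "scaffold_len_mean", "scaffold_len_sd",
              "gene_len"))
    assert_scalar_num(cfg[[f]], f, 1)
  assert_scalar_num(cfg$min_segment_len, "min_segment_len", 0)
  if (cfg$min_segment_len >= cfg$mean_segment_len)
    stop("min_segment_len must be below mean_segment_len", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

chrom_names <- function(n) sprintf("chr%02d", seq_len(n))

random_chromosome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate three founder genomes
#'
#' The founders share one coordinate system and are identical except at
#' catalogued biallelic SNP positions drawn independently per bp at
#' `snp_rate`.  Each site is private to one founder (that founder carries
#' the alternative allele of the pair); which founder is drawn from
#' `private_fracs`.
#'
#' @param cfg a [sim_config()].
#' @return a list with `genomes` (list of three named [Biostrings::DNAStringSet]
#'   objects `A`, `B`, `U`) and `catalog`, a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt`, `allele_a`, `allele_b`, `allele_u`.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- chrom_names(cfg$n_chrom)
  bases <- c("A", "C", "G", "T")
  seqs <- list(A = character(), B = character(), U = character())
  cat_list <- vector("list", cfg$n_chrom)
  for (ci in seq_along(chroms)) {
    anc <- random_chromosome(cfg$chrom_len)
    chars <- strsplit(anc, "", fixed = TRUE)[[1]]
    pos <- which(stats::runif(cfg$chrom_len) < cfg$snp_rate)
    n <- length(pos)
    if (n > 0L) {
      ref <- chars[pos]
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
      carrier <- sample(c("A", "B", "U"), n, replace = TRUE,
                        prob = cfg$private_fracs)
      al <- cbind(A = ref, B = ref, U = ref)
      al[cbind(seq_len(n), match(carrier, colnames(al)))] <- alt
      for (f in c("A", "B", "U")) {
        v <- chars
        v[pos] <- al[, f]
        seqs[[f]][chroms[ci]] <- paste(v, collapse = "")
      }
      cat_list[[ci]] <- data.frame(
        chrom = chroms[ci], pos = pos, ref = ref, alt = alt,
        allele_a = al[, "A"], allele_b = al[, "B"], allele_u = al[, "U"],
        stringsAsFactors = FALSE, row.names = NULL
      )
    } else {
      for (f in c("A", "B", "U")) seqs[[f]][chroms[ci]] <- anc
    }
  }
  catalog <- do.call(rbind, cat_list)
  if (is.null(catalog))
    catalog <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          allele_a = character(), allele_b = character(),
                          allele_u = character(), stringsAsFactors = FALSE)
  genomes <- lapply(seqs, function(s) Biostrings::DNAStringSet(s))
  list(genomes = genomes, catalog = catalog)
}

#' Simulate a mosaic offspring genome
#'
#' The offspring is a copy-paste mosaic of the three founders: segment
#' lengths are `min_segment_len` plus exponential draws, origins are i.i.d.
#' from `target_fracs`.  Adjacent same-origin segments are merged in the
#' returned truth table, which tiles every chromosome exactly.
#'
#' @param founders result of [simulate_founders()].
#' @param cfg the same [sim_config()].
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `truth`, a
#'   data.frame `chrom`, `start`, `end`, `origin` (1-based inclusive).
#' @export
simulate_offspring <- function(founders, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  chroms <- names(founders$genomes$A)
  L <- cfg$chrom_len
  mean_extra <- cfg$mean_segment_len - cfg$min_segment_len
  seg_list <- vector("list", length(chroms))
  seqs <- character(length(chroms))
  fo <- lapply(founders$genomes, as.character)
  for (ci in seq_along(chroms)) {
    pos <- 1L
    st <- integer(); en <- integer(); org <- character()
    while (pos <= L) {
      len <- cfg$min_segment_len + stats::rexp(1L, 1 / mean_extra)
      len <- max(1L, as.integer(round(len)))
      e <- min(L, pos + len - 1L)
      # keep the minimum segment length at chromosome ends: a remainder too
      # short to be its own segment is absorbed into the current one
      if (L - e < cfg$min_segment_len) e <- L
      o <- sample(c("A", "B", "U"), 1L, prob = cfg$target_fracs)
      if (length(org) && org[length(org)] == o) {
        en[length(en)] <- e
      } else {
        st <- c(st, pos); en <- c(en, e); org <- c(org, o)
      }
      pos <- e + 1L
    }
    pieces <- character(length(st))
    for (si in seq_along(st))
      pieces[si] <- substr(fo[[org[si]]][[ci]], st[si], en[si])
    seqs[ci] <- paste(pieces, collapse = "")
    seg_list[[ci]] <- data.frame(chrom = chroms[ci], start = st, end = en,
                                 origin = org, stringsAsFactors = FALSE)
  }
  names(seqs) <- chroms
  truth <- do.call(rbind, seg_list)
  list(genome = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Fragment a genome into scaffolds
#'
#' Cuts each chromosome into consecutive pieces with lognormal lengths
#' (arithmetic mean `scaffold_len_mean`, sd `scaffold_len_sd`), reverse-
#' complements each piece independently with probability 1/2, and applies
#' substitution errors at `scaffold_error_rate`.  The pieces partition the
#' genome: concatenating them (forward, error-free) restores it.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param cfg a [sim_config()].
#' @param revcomp_prob probability a scaffold is emitted reverse-complemented
#'   (set 0 to force forward strand).
#' @return list with `scaffolds` (DNAStringSet) and `truth`, a data.frame
#'   `scf_id`, `chrom`, `start`, `end`, `strand` giving each scaffold's true
#'   placement (coordinates of the forward-strand source interval).
#' @export
fragment_to_scaffolds <- function(genome, cfg, revcomp_prob = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  m <- cfg$scaffold_len_mean; s <- cfg$scaffold_len_sd
  sigma2 <- log(1 + (s / m)^2)
  mu <- log(m) - sigma2 / 2
  seqs <- as.character(genome)
  out_seq <- character(); out_truth <- vector("list", length(seqs))
  idx <- 0L
  for (ci in seq_along(seqs)) {
    L <- nchar(seqs[ci])
    st <- integer(); en <- integer()
    pos <- 1L
    while (pos <= L) {
      len <- max(200L, as.integer(round(stats::rlnorm(1L, mu, sqrt(sigma2)))))
      e <- min(L, pos + len - 1L)
      st <- c(st, pos); en <- c(en, e)
      pos <- e + 1L
    }
    strand <- ifelse(stats::runif(length(st)) < revcomp_prob, "-", "+")
    ids <- sprintf("scf%05d", idx + seq_along(st))
    idx <- idx + length(st)
    for (si in seq_along(st)) {
      piece <- substr(seqs[ci], st[si], en[si])
      if (strand[si] == "-") piece <- revcomp(piece)
      if (cfg$scaffold_error_rate > 0) {
        n_err <- stats::rbinom(1L, nchar(piece), cfg$scaffold_error_rate)
        if (n_err > 0L) {
          where <- sample.int(nchar(piece), n_err)
          ch <- strsplit(piece, "", fixed = TRUE)[[1]]
          ch[where] <- vapply(ch[where],
                              function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
          piece <- paste(ch, collapse = "")
        }
      }
      out_seq[ids[si]] <- piece
    }
    out_truth[[ci]] <- data.frame(scf_id = ids, chrom = names(seqs)[ci],
                                  start = st, end = en, strand = strand,
                                  stringsAsFactors = FALSE)
  }
  list(scaffolds = Biostrings::DNAStringSet(out_seq),
       truth = do.call(rbind, out_truth))
}

#' Sample marker gene queries from a genome
#'
#' Draws `n_genes` non-overlapping intervals of length `gene_len` and returns
#' their sequences as gene queries together with the truth positions, so a
#' locator can be validated against planted genes.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param cfg a [sim_config()].
#' @return list with `genes` (DNAStringSet named gene01..) and `truth`
#'   data.frame `gene_id`, `chrom`, `start`, `end`, `strand` (always "+").
#' @export
sample_gene_queries <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  chroms <- names(genome)
  lens <- Biostrings::width(genome)
  picks <- vector("list", cfg$n_genes)
  seqs <- character(cfg$n_genes)
  taken <- list()
  for (gi in seq_len(cfg$n_genes)) {
    repeat {
      ci <- sample(seq_along(chroms), 1L)
      if (lens[ci] < cfg$gene_len) next
      st <- sample.int(lens[ci] - cfg$gene_len + 1L, 1L)
      en <- st + cfg$gene_len - 1L
      clash <- any(vapply(taken, function(t)
        t$ci == ci && st <= t$en && en >= t$st, logical(1)))
      if (!clash) break
    }
    taken[[gi]] <- list(ci = ci, st = st, en = en)
    seqs[gi] <- substr(as.character(genome[ci]), st, en)
    picks[[gi]] <- data.frame(gene_id = sprintf("gene%02d", gi),
                              chrom = chroms[ci], start = st, end = en,
                              strand = "+", stringsAsFactors = FALSE)
  }
  names(seqs) <- sprintf("gene%02d", seq_len(cfg$n_genes))
  list(genes = Biostrings::DNAStringSet(seqs), truth = do.call(rbind, picks))
}

#' Write a three-sample VCF for the simulated trio
#'
#' Emits one VCFv4.2 record per catalogued site at which the three emitted
#' samples (offspring, parent A, parent B) are not all identical.  REF is the
#' ancestral allele, genotypes are homozygous diploid (the simulated lines
#' are inbred).  QUAL is `qual_default` except for a random fraction
#' `qual_low_frac` of records written with `qual_low`.
#'
#' @param founders result of [simulate_founders()].
#' @param offspring result of [simulate_offspring()] (its `genome` is
#'   consulted for the offspring allele at each site).
#' @param cfg a [sim_config()].
#' @param path output VCF path.
#' @param samples character length-3: names written to the VCF header, in the
#'   order offspring, parent A, parent B.
#' @return invisibly, the data.frame of emitted records.
#' @export
write_trio_vcf <- function(founders, offspring, cfg, path,
                           samples = c("offspring", "parent_a", "parent_b")) {
  stopifnot(inherits(cfg, "sim_config"), length(samples) == 3L)
  set.seed(cfg$seed + 4L)
  cat_df <- founders$catalog
  off_seq <- as.character(offspring$genome)
  off_allele <- substring(off_seq[cat_df$chrom], cat_df$pos, cat_df$pos)
  keep <- !(off_allele == cat_df$allele_a & off_allele == cat_df$allele_b)
  rec <- cat_df[keep, , drop = FALSE]
  off_allele <- off_allele[keep]
  n <- nrow(rec)
  qual <- rep(cfg$qual_default, n)
  if (cfg$qual_low_frac > 0 && n > 0L)
    qual[stats::runif(n) < cfg$qual_low_frac] <- cfg$qual_low
  gt <- function(allele, ref) ifelse(allele == ref, "0/0", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaicpaint-simulator",
    sprintf("##contig=<ID=%s,length=%d>",
            names(offspring$genome), Biostrings::width(offspring$genome)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (n > 0L) {
    body <- paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt,
                  format(qual, trim = TRUE), "PASS", ".", "GT",
                  gt(off_allele, rec$ref),
                  gt(rec$allele_a, rec$ref),
                  gt(rec$allele_b, rec$ref), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(data.frame(rec, off_allele = off_allele, qual = qual,
                       row.names = NULL))
}

#' Write truth segments as BED
#'
#' BED is 0-based half-open; the in-memory truth table is 1-based inclusive.
#'
#' @param truth truth segment data.frame from [simulate_offspring()].
#' @param path output path.
#' @export
write_truth_bed <- function(truth, path) {
  utils::write.table(
    data.frame(truth$chrom, truth$start - 1L, truth$end, truth$origin),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs the full simulator and writes reference (founder A), scaffolds,
#' trio VCF, gene queries, and truth files into `dir`.  Deterministic:
#' identical `cfg` gives byte-identical outputs.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `paths` (named file paths) and the
#'   in-memory objects (`founders`, `offspring`, `scaffolds`, `genes`).
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  founders <- simulate_founders(cfg)
  offspring <- simulate_offspring(founders, cfg)
  scf <- fragment_to_scaffolds(offspring$genome, cfg)
  genes <- sample_gene_queries(offspring$genome, cfg)
  p <- list(
    reference = file.path(dir, "reference.fa"),
    offspring = file.path(dir, "offspring.fa"),
    scaffolds = file.path(dir, "scaffolds.fa"),
    genes = file.path(dir, "genes.fa"),
    vcf = file.path(dir, "trio.vcf"),
    truth_segments = file.path(dir, "truth_segments.bed"),
    truth_placements = file.path(dir, "truth_placements.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv")
  )
  Biostrings::writeXStringSet(founders$genomes$A, p$reference)
  Biostrings::writeXStringSet(offspring$genome, p$offspring)
  Biostrings::writeXStringSet(scf$scaffolds, p$scaffolds)
  Biostrings::writeXStringSet(genes$genes, p$genes)
  write_trio_vcf(founders, offspring, cfg, p$vcf)
  write_truth_bed(offspring$truth, p$truth_segments)
  utils::write.table(scf$truth, p$truth_placements, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(genes$truth, p$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(paths = p, founders = founders, offspring = offspring,
                 scaffolds = scf, genes = genes))
}
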