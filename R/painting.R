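ORIGIN_LEVELS <- c("parent_a", "parent_b", "other")

#' Read and filter a three-sample VCF into SNP sites
#'
#' Reads a VCF (plain text or bgzipped), keeps biallelic SNP records with
#' QUAL at or above `min_qual` (inclusive), and extracts the homozygous
#' allele of each of the three named samples.  Heterozygous or missing
#' genotypes are returned as NA alleles (they become uninformative in
#' classification).  Indels and multi-allelic records are excluded.
#'
#' @param vcf path to a VCF file, or a `vcfR::vcfR` object.
#' @param offspring,parent_a,parent_b sample names in the VCF;
#'   defaults are the names written by [write_trio_vcf()].
#' @param min_qual minimum site quality (phred-scaled, inclusive).
#' @return a data.frame of sites: `chrom`, `pos`, `qual`, `off`, `pa`, `pb`
#'   (allele characters or NA).
#' @export
filter_sites <- function(vcf, offspring = "offspring",
                         parent_a = "parent_a", parent_b = "parent_b",
                         min_qual = 30) {
  if (is.character(vcf))
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fixed <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  avail <- colnames(gt)[-1L]
  for (s in c(offspring, parent_a, parent_b))
    if (!s %in% avail)
      stop(sprintf("sample '%s' not in VCF; available: %s",
                   s, paste(avail, collapse = ", ")), call. = FALSE)
  qual <- suppressWarnings(as.numeric(fixed$QUAL))
  ref <- fixed$REF; alt <- fixed$ALT
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- snp & !is.na(qual) & qual >= min_qual
  resolve <- function(sample) {
    g <- sub(":.*$", "", gt[, sample])
    a1 <- sub("^([0-9.])[/|]([0-9.])$", "\\1", g)
    a2 <- sub("^([0-9.])[/|]([0-9.])$", "\\2", g)
    hom <- !is.na(g) & a1 == a2 & a1 %in% c("0", "1")
    out <- rep(NA_character_, length(g))
    out[hom & a1 == "0"] <- ref[hom & a1 == "0"]
    out[hom & a1 == "1"] <- alt[hom & a1 == "1"]
    out
  }
  data.frame(
    chrom = fixed$CHROM[keep],
    pos = as.integer(fixed$POS[keep]),
    qual = qual[keep],
    off = resolve(offspring)[keep],
    pa = resolve(parent_a)[keep],
    pb = resolve(parent_b)[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Classify SNP sites by parental origin
#'
#' A site is parent-A-like when the offspring allele equals parent A's and
#' the parents differ; parent-B-like symmetrically; "other" when the
#' offspring allele matches neither parent.  Sites where all three samples
#' agree, or with heterozygous/missing genotypes (NA alleles), are
#' uninformative and excluded from all counts.
#'
#' @param sites data.frame from [filter_sites()] (columns `off`, `pa`, `pb`),
#'   or three character vectors via `off`, `pa`, `pb`.
#' @param off,pa,pb alternative vector interface.
#' @return the input data.frame with a `class` column
#'   (`"parent_a"`, `"parent_b"`, `"other"`, or NA for uninformative), or a
#'   character vector when vectors were supplied.
#' @export
classify_snps <- function(sites = NULL, off = NULL, pa = NULL, pb = NULL) {
  vecs <- is.null(sites)
  if (!vecs) { off <- sites$off; pa <- sites$pa; pb <- sites$pb }
  cls <- rep(NA_character_, length(off))
  known <- !is.na(off) & !is.na(pa) & !is.na(pb)
  cls[known & off == pa & pa != pb] <- "parent_a"
  cls[known & off == pb & pa != pb] <- "parent_b"
  cls[known & off != pa & off != pb] <- "other"
  if (vecs) return(cls)
  sites$class <- cls
  sites
}

#' Paint the genome in fixed windows
#'
#' Bins classified SNPs into consecutive windows of `w` bp anchored at
#' position 1 of each chromosome (window i covers `[(i-1)w+1, iw]`; a SNP at
#' position p falls in window `ceiling(p/w)`).  Each window is labelled with
#' its dominant class; a tie is labelled `"other"` (conservative: neither
#' parent is favoured) and a window with no classified SNP is `"missing"`.
#'
#' @param sites classified sites ([classify_snps()] output).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param w window size in bp.
#' @return data.frame of window blocks: `chrom`, `index`, `start`, `end`,
#'   `n_parent_a`, `n_parent_b`, `n_other`, `dominant`.
#' @export
window_paint <- function(sites, chrom_lengths, w) {
  assert_scalar_num(w, "w", 1)
  w <- as.integer(w)
  blocks <- vector("list", length(chrom_lengths))
  cl <- sites[!is.na(sites$class), , drop = FALSE]
  for (ci in seq_along(chrom_lengths)) {
    chrom <- names(chrom_lengths)[ci]
    L <- chrom_lengths[[ci]]
    n_win <- as.integer(ceiling(L / w))
    counts <- matrix(0L, nrow = n_win, ncol = 3L,
                     dimnames = list(NULL, ORIGIN_LEVELS))
    cc <- cl[cl$chrom == chrom, , drop = FALSE]
    if (nrow(cc)) {
      wi <- as.integer(ceiling(cc$pos / w))
      tab <- table(factor(wi, levels = seq_len(n_win)),
                   factor(cc$class, levels = ORIGIN_LEVELS))
      counts <- matrix(as.integer(tab), nrow = n_win,
                       dimnames = list(NULL, ORIGIN_LEVELS))
    }
    total <- rowSums(counts)
    top <- max.col(counts, ties.method = "first")
    n_at_max <- rowSums(counts == counts[cbind(seq_len(n_win), top)])
    dominant <- ORIGIN_LEVELS[top]
    dominant[total == 0L] <- "missing"
    dominant[total > 0L & n_at_max > 1L] <- "other"
    blocks[[ci]] <- data.frame(
      chrom = chrom, index = seq_len(n_win),
      start = (seq_len(n_win) - 1L) * w + 1L,
      end = seq_len(n_win) * w,
      n_parent_a = counts[, "parent_a"],
      n_parent_b = counts[, "parent_b"],
      n_other = counts[, "other"],
      dominant = dominant,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(blocks, make.row.names = FALSE))
}

#' Genome composition summary
#'
#' Per-class counts and integer percentages (half-up) over classified
#' units: for window blocks, the units are non-missing windows and the
#' class is the window's dominant label; for classified sites, the units
#' are the informative SNPs.  A bare named count vector
#' `(parent_a, parent_b, other)` is also accepted, so published count
#' tables can be summarised directly.
#'
#' @param x window blocks ([window_paint()]), classified sites
#'   ([classify_snps()]), or a named numeric vector of counts.
#' @return data.frame `class`, `n`, `pct` with attribute `total`.
#' @export
composition <- function(x) {
  if (is.numeric(x)) {
    counts <- x
    if (is.null(names(counts))) names(counts) <- ORIGIN_LEVELS
    counts <- counts[ORIGIN_LEVELS]
    names(counts) <- ORIGIN_LEVELS
  } else if (is.data.frame(x) && "dominant" %in% names(x)) {
    cl <- x$dominant[x$dominant != "missing"]
    counts <- vapply(ORIGIN_LEVELS, function(v) sum(cl == v), numeric(1))
  } else if (is.data.frame(x) && "class" %in% names(x)) {
    cl <- x$class[!is.na(x$class)]
    counts <- vapply(ORIGIN_LEVELS, function(v) sum(cl == v), numeric(1))
  } else stop("cannot summarise this object", call. = FALSE)
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total) else counts * 0
  out <- data.frame(class = ORIGIN_LEVELS, n = as.numeric(counts),
                    pct = as.numeric(pct), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "total") <- total
  out
}

#' Paint a genome profile plot
#'
#' One column per chromosome, windows stacked along physical position,
#' coloured by dominant class: blue = parent A, red = parent B,
#' green = other, white = missing.
#'
#' @param blocks window blocks from [window_paint()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_painting <- function(blocks, title = "Genome profile") {
  pal <- c(parent_a = "#2166ac", parent_b = "#b2182b",
           other = "#1b7837", missing = "#ffffff")
  ggplot2::ggplot(blocks) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = 0, xmax = 1,
      ymin = (.data$start - 1) / 1e6, ymax = .data$end / 1e6,
      fill = .data$dominant
    ), colour = NA) +
    ggplot2::scale_fill_manual(values = pal, name = "origin") +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom)) +
    ggplot2::labs(y = "position (Mb)", x = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @importFrom rlang .data
NULL
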