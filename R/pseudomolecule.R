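#' Build pseudomolecules from scaffold placements
#'
#' Re-orients and connects placed scaffolds in reference order, one
#' pseudomolecule per reference chromosome.  Consecutive components are
#' separated by an N gap equal to the reference gap between their projected
#' intervals (0 if abutting), and a leading N gap is inserted when the first
#' scaffold starts after position 1, so pseudomolecule coordinates track
#' reference coordinates.  When projected intervals overlap, the
#' lower-scoring scaffold is trimmed by the overlap on its conflicting end,
#' or dropped entirely if fully contained within a higher-scoring one.
#' Minus-strand scaffolds are reverse-complemented before insertion.
#'
#' @param placements data.frame as produced by [place_scaffolds()] (at most
#'   one row per scaffold).
#' @param scaffolds named [Biostrings::DNAStringSet] or FASTA path with every
#'   placed scaffold.
#' @param reference_lengths named vector of reference chromosome lengths, or
#'   a `kmer_index` (its lengths are used).
#' @return an `assembly_build`: list with `pseudomolecules` (DNAStringSet),
#'   `agp` (data.frame of AGP v2.1 rows), `unplaced` (scaffold ids),
#'   `placed_bases` (total length of placed scaffolds, before trimming) and
#'   `genome_size` (sum of component W-row lengths; gap Ns excluded).
#' @export
build_pseudomolecules <- function(placements, scaffolds, reference_lengths) {
  scaffolds <- as_genome(scaffolds)
  if (inherits(reference_lengths, "kmer_index"))
    reference_lengths <- reference_lengths$lengths
  pl <- as.data.table(placements)
  if (nrow(pl) > 0L) {
    missing <- setdiff(pl$scf_id, names(scaffolds))
    if (length(missing))
      stop("placements reference unknown scaffolds: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    if (anyDuplicated(pl$scf_id))
      stop("more than one placement for a scaffold", call. = FALSE)
  }
  scf_seq <- as.character(scaffolds)
  unplaced <- setdiff(names(scaffolds), pl$scf_id)
  agp <- list(); pseudo <- character()
  for (chr in sort(unique(pl$ref_chrom))) {
    rows <- pl[ref_chrom == chr]
    setorder(rows, ref_start, -score)
    # oriented sequences with trim bookkeeping (lt/rt on the oriented seq)
    comp <- lapply(seq_len(nrow(rows)), function(i) {
      s <- scf_seq[[rows$scf_id[i]]]
      if (rows$strand[i] == "-") s <- revcomp(s)
      list(id = rows$scf_id[i], seq = s, len = nchar(s),
           strand = rows$strand[i],
           start = rows$ref_start[i], end = rows$ref_end[i],
           score = rows$score[i], lt = 0L, rt = 0L, drop = FALSE)
    })
    # resolve overlaps against the last kept component
    kept <- list()
    for (cur in comp) {
      if (length(kept) == 0L) { kept <- list(cur); next }
      prev <- kept[[length(kept)]]
      if (cur$start > prev$end) { kept[[length(kept) + 1L]] <- cur; next }
      if (cur$end <= prev$end) {
        # containment: drop whichever scores lower
        if (cur$score <= prev$score) {
          cur$drop <- TRUE
          unplaced <- c(unplaced, cur$id)
        } else {
          # previous loses its tail from cur's start onward
          cut <- prev$end - cur$start + 1L
          prev$rt <- prev$rt + cut
          prev$end <- cur$start - 1L
          if (prev$lt + prev$rt >= prev$len) {
            unplaced <- c(unplaced, prev$id)
            kept[[length(kept)]] <- NULL
          } else kept[[length(kept)]] <- prev
          kept[[length(kept) + 1L]] <- cur
        }
        next
      }
      ov <- prev$end - cur$start + 1L
      if (cur$score < prev$score) {
        cur$lt <- cur$lt + ov
        cur$start <- prev$end + 1L
      } else {
        prev$rt <- prev$rt + ov
        prev$end <- cur$start - 1L
        kept[[length(kept)]] <- prev
      }
      dropped_cur <- cur$lt + cur$rt >= cur$len
      if (dropped_cur) unplaced <- c(unplaced, cur$id)
      else kept[[length(kept) + 1L]] <- cur
    }
    if (length(kept) == 0L) next
    # emit AGP rows and sequence
    obj <- chr
    parts <- list(); pieces <- character()
    obj_pos <- 0L; part_no <- 0L
    prev_end <- 0L
    for (cp in kept) {
      gap <- cp$start - prev_end - 1L
      if (gap > 0L) {
        part_no <- part_no + 1L
        parts[[part_no]] <- data.frame(
          object = obj, obj_start = obj_pos + 1L, obj_end = obj_pos + gap,
          part_number = part_no, component_type = "N",
          component_id = as.character(gap), component_beg = "scaffold",
          component_end = "yes", orientation = "align_genus",
          stringsAsFactors = FALSE)
        pieces <- c(pieces, strrep("N", gap))
        obj_pos <- obj_pos + gap
      }
      sub <- substr(cp$seq, cp$lt + 1L, cp$len - cp$rt)
      w <- nchar(sub)
      # component coordinates are in the scaffold's own forward frame
      if (cp$strand == "+") {
        cb <- cp$lt + 1L; ce <- cp$len - cp$rt
      } else {
        cb <- cp$rt + 1L; ce <- cp$len - cp$lt
      }
      part_no <- part_no + 1L
      parts[[part_no]] <- data.frame(
        object = obj, obj_start = obj_pos + 1L, obj_end = obj_pos + w,
        part_number = part_no, component_type = "W",
        component_id = cp$id, component_beg = as.character(cb),
        component_end = as.character(ce), orientation = cp$strand,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, sub)
      obj_pos <- obj_pos + w
      prev_end <- cp$end
    }
    agp[[chr]] <- do.call(rbind, parts)
    pseudo[obj] <- paste(pieces, collapse = "")
  }
  agp_df <- if (length(agp)) do.call(rbind, c(agp, make.row.names = FALSE))
            else data.frame()
  w_rows <- agp_df[agp_df$component_type == "W", , drop = FALSE]
  genome_size <- if (nrow(w_rows)) sum(w_rows$obj_end - w_rows$obj_start + 1)
                 else 0
  placed_ids <- setdiff(names(scaffolds), unique(unplaced))
  structure(list(
    pseudomolecules = Biostrings::DNAStringSet(pseudo),
    agp = agp_df,
    unplaced = sort(unique(unplaced)),
    placed_bases = sum(nchar(scf_seq[placed_ids])),
    genome_size = genome_size
  ), class = "assembly_build")
}

#' Assembled-genome coverage of a reference
#'
#' Percentage of the reference covered by assembled (non-gap) bases,
#' rounded half-up to one decimal, the convention used in assembly summary
#' tables.
#'
#' @param genome_size assembled bases (gap Ns excluded).
#' @param reference_size reference genome size in bp.
#' @return percentage with one decimal.
#' @export
coverage_percent <- function(genome_size, reference_size) {
  assert_scalar_num(reference_size, "reference_size", 1e-9)
  assert_scalar_num(genome_size, "genome_size", 0)
  round_half_up(100 * genome_size / reference_size, 1)
}

#' Write an AGP v2.1 file
#' @param build an `assembly_build` or its `agp` data.frame.
#' @param path output path.
#' @export
write_agp <- function(build, path) {
  agp <- if (inherits(build, "assembly_build")) build$agp else build
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an AGP file written by [write_agp()]
#' @param path input path.
#' @return data.frame of AGP rows.
#' @export
read_agp <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("object", "obj_start", "obj_end",
                                        "part_number", "component_type",
                                        "component_id", "component_beg",
                                        "component_end", "orientation"),
                          colClasses = c("character", "integer", "integer",
                                         "integer", "character", "character",
                                         "character", "character", "character"))
  df
}

#' Reconstruct pseudomolecule sequences from AGP rows and scaffolds
#'
#' Used to validate that an AGP file and the scaffold FASTA reproduce the
#' emitted pseudomolecule FASTA byte-for-byte.
#'
#' @param agp data.frame of AGP rows ([read_agp()] / `assembly_build$agp`).
#' @param scaffolds named [Biostrings::DNAStringSet] or FASTA path.
#' @return a [Biostrings::DNAStringSet] of reconstructed objects.
#' @export
sequence_from_agp <- function(agp, scaffolds) {
  scaffolds <- as_genome(scaffolds)
  scf_seq <- as.character(scaffolds)
  out <- character()
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    pieces <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      if (rows$component_type[i] == "N") {
        pieces[i] <- strrep("N", as.integer(rows$component_id[i]))
      } else {
        s <- substr(scf_seq[[rows$component_id[i]]],
                    as.integer(rows$component_beg[i]),
                    as.integer(rows$component_end[i]))
        if (rows$orientation[i] == "-") s <- revcomp(s)
        pieces[i] <- s
      }
    }
    out[obj] <- paste(pieces, collapse = "")
  }
  Biostrings::DNAStringSet(out)
}
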