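#' Parse a region string
#'
#' @param x a string like `"chr08:12400000-24100000"` (commas allowed in the
#'   numbers), or a list with `chrom`, `start`, `end` returned unchanged.
#' @return list with `chrom`, `start`, `end` (1-based inclusive).
#' @export
parse_region <- function(x) {
  if (is.list(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    if (x$start >= x$end) stop("region start must be below end", call. = FALSE)
    return(x)
  }
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1L]]
  if (length(m) != 4L)
    stop("region must look like 'chrom:start-end'", call. = FALSE)
  start <- as.numeric(gsub(",", "", m[3L]))
  end <- as.numeric(gsub(",", "", m[4L]))
  if (start >= end) stop("region start must be below end", call. = FALSE)
  list(chrom = m[2L], start = start, end = end)
}

#' Zoom window blocks into a region
#'
#' Returns the window blocks of the region's chromosome whose index lies in
#' `(start/w, end/w]`, i.e. windows `floor(start/w)+1 .. ceiling(end/w)` —
#' the genome-anchored window grid is kept, windows at the region edges are
#' included whole, and labels are unchanged.
#'
#' @param blocks window blocks from [window_paint()] (one window size).
#' @param region a region string or list, see [parse_region()].
#' @return the zoomed window blocks, ordered by start; empty (with a
#'   warning) when the chromosome is absent.
#' @export
zoom_windows <- function(blocks, region) {
  region <- parse_region(region)
  cb <- blocks[blocks$chrom == region$chrom, , drop = FALSE]
  if (nrow(cb) == 0L) {
    warning(sprintf("chromosome '%s' not present in windows", region$chrom))
    return(cb)
  }
  w <- cb$end[1L] - cb$start[1L] + 1L
  lo <- floor(region$start / w) + 1L
  hi <- ceiling(region$end / w)
  out <- cb[cb$index >= lo & cb$index <= hi, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Contiguous same-origin segments of a painted region
#'
#' Run-length encodes the dominant labels of consecutive windows; runs of
#' missing windows are preserved as their own segments, matching painting
#' plots where missing data shows as white space.
#'
#' @param blocks window blocks (typically a [zoom_windows()] result), one
#'   chromosome, ordered by start.
#' @return data.frame `chrom`, `start`, `end`, `origin`, `n_windows`.
#' @export
origin_segments <- function(blocks) {
  if (nrow(blocks) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), origin = character(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  stopifnot(length(unique(blocks$chrom)) == 1L)
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  r <- rle(blocks$dominant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    chrom = blocks$chrom[1L],
    start = blocks$start[starts],
    end = blocks$end[ends],
    origin = r$values,
    n_windows = r$lengths,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Zoom report for a QTL region
#'
#' Convenience wrapper: zooms the painting into the region and reports both
#' the windows and their run-length origin segments.
#'
#' @param blocks window blocks from [window_paint()].
#' @param region region string or list.
#' @return list with `region`, `windows`, `segments`.
#' @export
qtl_report <- function(blocks, region) {
  region <- parse_region(region)
  win <- zoom_windows(blocks, region)
  list(region = region, windows = win, segments = origin_segments(win))
}
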