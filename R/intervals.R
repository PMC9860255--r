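#' Construct a table of genomic intervals
#'
#' Intervals are kept in BED convention throughout the package: 0-based
#' starts, exclusive ends, so `end - start` is the length in bp. Strand is
#' `"+"`, `"-"` or `"*"` (unstranded).
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, exclusive end positions (`end > start`).
#' @param strand optional strand vector; defaults to `"*"`.
#' @param ... further equal-length columns carried along (e.g. `name`,
#'   `score`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   plus any extra columns.
#' @export
gintervals <- function(chrom, start, end, strand = NULL, ...) {
  n <- length(chrom)
  if (is.null(strand)) strand <- rep("*", n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_gintervals(df)
  df
}

validate_gintervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0)) stop("interval starts must be >= 0")
  if (any(x$end <= x$start)) stop("intervals must satisfy end > start")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(x)
}

#' @keywords internal
#' @noRd
as_granges <- function(x, seqlengths = NULL) {
  strand <- if ("strand" %in% names(x)) x$strand else rep("*", nrow(x))
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand)
}

#' @keywords internal
#' @noRd
from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Merge intervals chained by small gaps
#'
#' Intervals on the same chromosome are merged transitively whenever the gap
#' between them (`start_next - end_prev`; overlaps count as gap <= 0) is
#' strictly smaller than `max_gap`. `max_gap = 0` therefore merges only
#' intervals that genuinely overlap by at least 1 bp, while `max_gap = 50`
#' merges intervals less than 50 bp apart (gap of 49 merges, 50 does not).
#'
#' @param x interval table as from [gintervals()].
#' @param max_gap non-negative integer; strict upper bound on gaps that
#'   still merge.
#' @return Sorted, pairwise-disjoint interval table (strand ignored).
#' @export
merge_intervals <- function(x, max_gap = 0L) {
  validate_gintervals(x)
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative integer")
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr <- as_granges(x)
  GenomicRanges::strand(gr) <- "*"
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                               min.gapwidth = as.integer(max_gap))
  out <- from_granges(red)
  out$strand <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance between two intervals
#'
#' @param a,b single-row interval tables (or lists with `chrom`, `start`,
#'   `end`).
#' @return 0 if the intervals overlap or are adjacent, the gap in bp
#'   otherwise, and `NA_integer_` (a typed sentinel) when the intervals lie
#'   on different chromosomes.
#' @export
interval_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_integer_)
  gap <- max(b$start - a$end, a$start - b$end, 0L)
  as.integer(gap)
}

#' Overlap length of two intervals in bp
#'
#' @param a,b single-row interval tables (or lists with `chrom`, `start`,
#'   `end`).
#' @return `max(0, min(end) - max(start))` on the same chromosome, else 0.
#' @export
overlap_length <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  as.integer(max(0L, min(a$end, b$end) - max(a$start, b$start)))
}

# vectorized overlap bp of each interval in x with the union of y;
# y is merged first so overlapping y intervals are not double counted
covered_bp <- function(x, y) {
  if (nrow(x) == 0) return(integer(0))
  if (nrow(y) == 0) return(integer(nrow(x)))
  grx <- as_granges(x)
  gry <- GenomicRanges::reduce(as_granges(y), ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(grx, gry, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(grx[S4Vectors::queryHits(hits)],
                                  gry[S4Vectors::subjectHits(hits)],
                                  ignore.strand = TRUE)
  w <- GenomicRanges::width(ov)
  out <- integer(nrow(x))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

# logical: does each interval in x overlap >=min_bp with any interval in y
overlaps_any <- function(x, y, min_bp = 1L) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(logical(nrow(x)))
  hits <- GenomicRanges::findOverlaps(as_granges(x), as_granges(y),
                                      minoverlap = as.integer(min_bp),
                                      ignore.strand = TRUE)
  seq_len(nrow(x)) %in% S4Vectors::queryHits(hits)
}
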