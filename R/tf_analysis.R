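#' TF occupancy matrix over ACRs
#'
#' An ACR is bound by a TF iff the union of that TF's peaks covers strictly
#' more than `min_coverage` of the ACR's length (the paper-style "more than
#' 50% covered" rule; coverage of exactly the threshold is unbound).
#'
#' @param acrs ACR table with `acr_id`.
#' @param tf_sets named list of per-TF interval tables (names are TF ids).
#' @param min_coverage coverage fraction in `[0, 1)` (default 0.5).
#' @return Logical matrix, rows = ACR ids, columns = TF ids.
#' @export
tf_occupancy <- function(acrs, tf_sets, min_coverage = 0.5) {
  if (min_coverage < 0 || min_coverage >= 1)
    stop("min_coverage must be in [0, 1)")
  if (is.null(names(tf_sets))) stop("tf_sets must be named by TF id")
  len <- acrs$end - acrs$start
  m <- vapply(tf_sets, function(peaks) {
    if (nrow(peaks) == 0) return(rep(FALSE, nrow(acrs)))
    covered_bp(acrs, peaks) > min_coverage * len
  }, logical(nrow(acrs)))
  m <- matrix(m, nrow = nrow(acrs),
              dimnames = list(acrs$acr_id, names(tf_sets)))
  m
}

#' Number of distinct TFs bound per ACR
#'
#' @param occupancy logical matrix from [tf_occupancy()].
#' @return Named integer vector of row sums.
#' @export
tf_counts_per_acr <- function(occupancy) {
  if (any(is.na(occupancy))) stop("occupancy matrix must be complete")
  rowSums(occupancy)
}

#' Odds ratio from a 2x2 bound/unbound contingency table
#'
#' `OR = (a/b) / (c/d)` where `a` = focal-class ACRs bound, `b` = focal not
#' bound, `c` = comparator bound, `d` = comparator not bound. With
#' `correction = "haldane"` (default) 0.5 is added to every cell iff any
#' cell is zero (flagged in the output); with `correction = "none"` a zero
#' `b` or `d` is an error.
#'
#' @param a,b,c,d non-negative counts.
#' @param correction `"haldane"` or `"none"`.
#' @return List: `odds_ratio`, `log_odds_ratio` (natural log),
#'   `corrected` (logical).
#' @export
tf_odds_ratio <- function(a, b, c, d, correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("contingency cells must be >= 0")
  corrected <- FALSE
  if (any(cells == 0)) {
    if (correction == "none") {
      if (b == 0 || d == 0) stop("zero cell without correction")
    } else {
      cells <- cells + 0.5
      corrected <- TRUE
    }
  }
  or <- (cells["a"] / cells["b"]) / (cells["c"] / cells["d"])
  list(odds_ratio = unname(or), log_odds_ratio = unname(log(or)),
       corrected = corrected)
}

#' Per-TF enrichment scan between two ACR classes
#'
#' For each TF builds the 2x2 table with `class_a` ACRs in the focal slot
#' and `class_b` as comparator, and reports the (log) odds ratio, sorted by
#' log-OR descending (ties by TF id).
#'
#' @param occupancy logical matrix from [tf_occupancy()].
#' @param class_labels character vector classifying each row of
#'   `occupancy` (same order).
#' @param class_a,class_b the two class labels to compare.
#' @param correction passed to [tf_odds_ratio()].
#' @return data.frame: `tf_id`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `log_odds_ratio`, `corrected`.
#' @export
enrichment_scan <- function(occupancy, class_labels, class_a, class_b,
                            correction = "haldane") {
  stopifnot(length(class_labels) == nrow(occupancy))
  ia <- class_labels == class_a
  ib <- class_labels == class_b
  if (!any(ia)) stop("no ACRs in class ", class_a)
  if (!any(ib)) stop("no ACRs in class ", class_b)
  rows <- lapply(colnames(occupancy), function(tf) {
    bound <- occupancy[, tf]
    a <- sum(bound & ia); b <- sum(!bound & ia)
    cc <- sum(bound & ib); d <- sum(!bound & ib)
    or <- tf_odds_ratio(a, b, cc, d, correction = correction)
    data.frame(tf_id = tf, a = a, b = b, c = cc, d = d,
               odds_ratio = or$odds_ratio,
               log_odds_ratio = or$log_odds_ratio,
               corrected = or$corrected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$log_odds_ratio, out$tf_id), , drop = FALSE]
}

#' Catalog motif hits inside SE spans
#'
#' @param ses SE table with `se_id`.
#' @param motif_hits data.frame: `motif_id`, `chrom`, `start`, `end` (+
#'   optional `strand`, `score`), genome coordinates.
#' @return List with `hits` (motif hits annotated with `se_id`) and
#'   `counts` (per-SE distinct-motif count, zero-filled).
#' @export
motif_catalog <- function(ses, motif_hits) {
  counts <- stats::setNames(integer(nrow(ses)), ses$se_id)
  empty <- data.frame(se_id = character(), motif_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(motif_hits) == 0)
    return(list(hits = empty, counts = counts))
  hits <- GenomicRanges::findOverlaps(as_granges(motif_hits), as_granges(ses),
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(list(hits = empty, counts = counts))
  ann <- motif_hits[S4Vectors::queryHits(hits), , drop = FALSE]
  ann$se_id <- ses$se_id[S4Vectors::subjectHits(hits)]
  per <- tapply(ann$motif_id, ann$se_id, function(m) length(unique(m)))
  counts[names(per)] <- as.integer(per)
  list(hits = ann, counts = counts)
}
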