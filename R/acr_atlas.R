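#' Build the multi-sample union set of ACRs
#'
#' Peaks from all samples are overlap-merged (gap < 0 only, i.e. >= 1 bp
#' shared) into accessible chromatin regions (ACRs); each ACR records every
#' sample contributing at least 1 bp.
#'
#' @param samples named list; each element an interval table of that
#'   sample's retained peaks. Names are sample ids.
#' @return Interval table of ACRs with `acr_id`, `n_samples` and
#'   `supporting_samples` (comma-separated sample ids).
#' @export
build_union_acrs <- function(samples) {
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be a named list (sample ids)")
  peak_rows <- vapply(samples, nrow, integer(1))
  if (sum(peak_rows) == 0) stop("no peaks in any sample")
  pooled <- do.call(rbind, lapply(names(samples), function(id) {
    p <- samples[[id]]
    if (nrow(p) == 0) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               sample_id = id, stringsAsFactors = FALSE)
  }))
  acrs <- merge_intervals(pooled, max_gap = 0L)
  hits <- GenomicRanges::findOverlaps(as_granges(pooled), as_granges(acrs),
                                      ignore.strand = TRUE)
  sup_list <- split(pooled$sample_id[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits))
  sup <- character(nrow(acrs))
  sup[as.integer(names(sup_list))] <-
    vapply(sup_list, function(s) paste(sort(unique(s)), collapse = ","),
           character(1))
  acrs$acr_id <- sprintf("ACR%05d", seq_len(nrow(acrs)))
  acrs$supporting_samples <- sup
  acrs$n_samples <- lengths(strsplit(sup, ",", fixed = TRUE))
  acrs
}

#' Classify ACRs as promoter or nonpromoter
#'
#' An ACR is a promoter ACR iff it overlaps (by at least `min_overlap_bp`)
#' the strand-aware window of `upstream_bp` bp upstream of any TSS; all
#' other ACRs are nonpromoter.
#'
#' @param acrs interval table of ACRs.
#' @param gm a [gene_models()] object (all genes stranded).
#' @param upstream_bp promoter window size (default 500).
#' @param min_overlap_bp minimum overlap to call promoter (default 1).
#' @return `acrs` with an added `acr_class` column
#'   (`"promoter"`/`"nonpromoter"`).
#' @export
classify_acrs <- function(acrs, gm, upstream_bp = 500L, min_overlap_bp = 1L) {
  win <- promoter_windows(gm, upstream_bp)
  is_prom <- overlaps_any(acrs, win, min_bp = min_overlap_bp)
  acrs$acr_class <- ifelse(is_prom, "promoter", "nonpromoter")
  acrs
}

#' DNase sensitivity of an ACR in one sample
#'
#' Reads per bp per million mapped reads: the number of read starts inside
#' the ACR, divided by ACR length, divided by (total mapped reads / 1e6).
#' Both normalizing factors are also returned separately.
#'
#' @param acr single-row interval table.
#' @param track the sample's [read_start_track()] for the ACR's chromosome.
#' @return List with `sensitivity`, `n_reads`, `reads_per_bp`,
#'   `per_million_scale`.
#' @export
dnase_sensitivity <- function(acr, track) {
  if (track$total_mapped_reads == 0) stop("total_mapped_reads is zero")
  if (acr$chrom != track$chrom) {
    n <- 0L
  } else {
    n <- sum(track$positions >= acr$start & track$positions < acr$end)
  }
  len <- acr$end - acr$start
  per_bp <- n / len
  scale <- track$total_mapped_reads / 1e6
  list(sensitivity = per_bp / scale, n_reads = n,
       reads_per_bp = per_bp, per_million_scale = scale)
}
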