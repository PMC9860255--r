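#' Cluster nonpromoter ACRs by genomic proximity
#'
#' Nonpromoter ACRs less than 50 bp apart (gap <= `max_gap`, default 49)
#' are chained into clusters; isolated ACRs form singleton clusters. The
#' cluster span runs from the first constituent start to the last
#' constituent end.
#'
#' @param acrs classified ACR table (from [classify_acrs()]); promoter ACRs
#'   are ignored.
#' @param max_gap largest gap (inclusive, bp) that still chains two ACRs.
#' @return Cluster table: `cluster_id`, `chrom`, `start`, `end`, `length`,
#'   `n_constituents`, `constituent_ids` (comma-separated `acr_id`s).
#' @export
cluster_nonpromoter_acrs <- function(acrs, max_gap = 49L) {
  np <- acrs[acrs$acr_class == "nonpromoter", , drop = FALSE]
  if (nrow(np) == 0) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      n_constituents = integer(), constituent_ids = character(),
                      stringsAsFactors = FALSE))
  }
  # inclusive max_gap: gap of exactly max_gap still merges
  spans <- merge_intervals(np, max_gap = as.integer(max_gap) + 1L)
  hits <- GenomicRanges::findOverlaps(as_granges(np), as_granges(spans),
                                      ignore.strand = TRUE)
  member <- split(seq_len(nrow(np))[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits))
  spans$n_constituents <- 0L
  spans$constituent_ids <- ""
  for (k in names(member)) {
    i <- as.integer(k)
    idx <- member[[k]][order(np$start[member[[k]]])]
    spans$n_constituents[i] <- length(idx)
    spans$constituent_ids[i] <- paste(np$acr_id[idx], collapse = ",")
  }
  spans$length <- spans$end - spans$start
  spans$cluster_id <- sprintf("CL%05d", seq_len(nrow(spans)))
  spans[, c("cluster_id", "chrom", "start", "end", "length",
            "n_constituents", "constituent_ids")]
}

#' Select super-enhancers from ACR clusters
#'
#' The primary rule takes the top `top_fraction` of clusters by length
#' (`k = ceiling(top_fraction * n)` after sorting by length descending,
#' ties broken by earlier genomic coordinate, then chromosome name). The
#' alternative `mode = "length"` fixes a bp threshold instead, selecting
#' every cluster with `length >= min_length` — the threshold form of the
#' same rule (the quantile rule's realized threshold is always reported).
#'
#' @param clusters cluster table from [cluster_nonpromoter_acrs()].
#' @param top_fraction fraction of clusters to call SEs (default 0.025).
#' @param mode `"quantile"` (default) or `"length"`.
#' @param min_length bp threshold used when `mode = "length"`.
#' @return List with `ses` (cluster table plus `se_id`, sorted by length
#'   descending) and `se_length_threshold` (length of the last selected
#'   cluster, or `min_length` in length mode).
#' @export
select_super_enhancers <- function(clusters, top_fraction = 0.025,
                                   mode = c("quantile", "length"),
                                   min_length = 1500L) {
  mode <- match.arg(mode)
  if (nrow(clusters) == 0) stop("no clusters")
  ord <- order(-clusters$length, clusters$start, clusters$chrom)
  sorted <- clusters[ord, , drop = FALSE]
  if (mode == "quantile") {
    if (top_fraction <= 0 || top_fraction >= 1)
      stop("top_fraction must be in (0, 1)")
    k <- ceiling(top_fraction * nrow(clusters))
    ses <- sorted[seq_len(k), , drop = FALSE]
    thr <- ses$length[k]
  } else {
    ses <- sorted[sorted$length >= min_length, , drop = FALSE]
    thr <- as.integer(min_length)
  }
  if (nrow(ses) > 0) ses$se_id <- sprintf("SE%04d", seq_len(nrow(ses)))
  else ses$se_id <- character(0)
  rownames(ses) <- NULL
  list(ses = ses, se_length_threshold = thr)
}

#' Assign the cognate gene of each SE
#'
#' The cognate gene is the gene whose body is closest to the SE span
#' (distance 0 when overlapping). Ties are broken by smaller distance from
#' the SE midpoint to the gene TSS, then lexicographic gene id. SEs on
#' gene-free chromosomes get an `NA` cognate and are flagged.
#'
#' @param ses SE table.
#' @param gm a [gene_models()] object.
#' @return `ses` with `cognate_gene`, `cognate_distance` columns.
#' @export
assign_cognate_gene <- function(ses, gm) {
  g <- gm$genes
  ses$cognate_gene <- NA_character_
  ses$cognate_distance <- NA_integer_
  for (i in seq_len(nrow(ses))) {
    cand <- g[g$chrom == ses$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- pmax(cand$start - ses$end[i], ses$start[i] - cand$end, 0L)
    mid <- (ses$start[i] + ses$end[i]) / 2
    tssd <- abs(mid - cand$tss)
    best <- order(d, tssd, cand$gene_id)[1]
    ses$cognate_gene[i] <- cand$gene_id[best]
    ses$cognate_distance[i] <- as.integer(d[best])
  }
  ses
}

#' Classify the genomic position of each SE
#'
#' An SE is genic iff at least `genic_min_frac` of its length overlaps a
#' single gene body; genic SEs fully inside one intron are
#' `genic_single_intron`, fully inside one exon `genic_exonic`, otherwise
#' `genic_multifeature`. Intergenic SEs are subclassified from their two
#' flanking genes: `five_prime_of_a_flank` when the SE lies strand-upstream
#' of at least one flank, `three_prime_of_both` when it is strand-downstream
#' of both. `nearest_end_distance` is the distance to the closest TSS or
#' TTS of any gene on the chromosome.
#'
#' @param ses SE table.
#' @param gm a [gene_models()] object with exon structure.
#' @param genic_min_frac minimum single-gene overlap fraction (default 0.5).
#' @return `ses` with `position_class`, `intergenic_subclass`,
#'   `nearest_end_distance` columns.
#' @export
classify_se_position <- function(ses, gm, genic_min_frac = 0.5) {
  g <- gm$genes
  ses$position_class <- NA_character_
  ses$intergenic_subclass <- NA_character_
  ses$nearest_end_distance <- NA_integer_
  for (i in seq_len(nrow(ses))) {
    se <- ses[i, ]
    len <- se$end - se$start
    cand <- g[g$chrom == se$chrom, , drop = FALSE]
    if (nrow(cand) > 0) {
      ends <- c(cand$tss, cand$tts)
      ses$nearest_end_distance[i] <-
        as.integer(min(pmax(ends - se$end, se$start - ends, 0L)))
      ov <- pmax(0L, pmin(cand$end, se$end) - pmax(cand$start, se$start))
      best <- which.max(ov)
    } else {
      ov <- 0L
    }
    if (nrow(cand) > 0 && max(ov) >= genic_min_frac * len) {
      host <- cand[best, ]
      intr <- gene_introns(gm, host$gene_id)
      ex <- gm$exons[gm$exons$gene_id == host$gene_id, , drop = FALSE]
      inside <- function(tab) nrow(tab) > 0 &&
        any(tab$start <= se$start & tab$end >= se$end)
      ses$position_class[i] <-
        if (inside(intr)) "genic_single_intron"
        else if (inside(ex)) "genic_exonic"
        else "genic_multifeature"
    } else {
      ses$position_class[i] <- "intergenic"
      left <- cand[cand$end <= se$start, , drop = FALSE]
      right <- cand[cand$start >= se$end, , drop = FALSE]
      lg <- if (nrow(left)) left[which.max(left$end), ] else NULL
      rg <- if (nrow(right)) right[which.min(right$start), ] else NULL
      # SE is 5' of the right flank when that flank reads rightward (+),
      # and 5' of the left flank when that flank reads leftward (-)
      five_of_right <- !is.null(rg) && rg$strand == "+"
      five_of_left <- !is.null(lg) && lg$strand == "-"
      three_of_both <- !is.null(lg) && !is.null(rg) &&
        lg$strand == "+" && rg$strand == "-"
      ses$intergenic_subclass[i] <-
        if (five_of_right || five_of_left) "five_prime_of_a_flank"
        else if (three_of_both) "three_prime_of_both"
        else NA_character_
    }
  }
  ses
}

#' Summarize an ACR/SE atlas
#'
#' Headline counts of the analysis: ACR totals and promoter fraction,
#' cluster and SE counts, the realized SE length threshold, SE size
#' statistics, constituent counts, the genic/intergenic partition with the
#' genic percentage rounded to the nearest integer, and the fraction of
#' intergenic SEs whose span lies within `near_end_bp` of the nearest gene
#' TSS or TTS.
#'
#' @param acrs classified ACR table (or NULL).
#' @param clusters cluster table (or NULL).
#' @param ses SE table carrying `position_class` and
#'   `nearest_end_distance` (and `n_constituents`).
#' @param se_length_threshold realized threshold from
#'   [select_super_enhancers()].
#' @param near_end_bp distance used for the near-gene-end fraction
#'   (default 3200 bp).
#' @return List of class `atlas_summary`.
#' @export
summarize_atlas <- function(acrs = NULL, clusters = NULL, ses,
                            se_length_threshold = NA_real_,
                            near_end_bp = 3200L) {
  n_ses <- nrow(ses)
  genic <- grepl("^genic", ses$position_class)
  n_genic <- sum(genic)
  n_intergenic <- n_ses - n_genic
  lens <- ses$end - ses$start
  inter <- ses[!genic, , drop = FALSE]
  frac_near <- if (nrow(inter) > 0 && "nearest_end_distance" %in% names(inter))
    mean(inter$nearest_end_distance <= near_end_bp) else NA_real_
  out <- list(
    n_acrs = if (is.null(acrs)) NA_integer_ else nrow(acrs),
    promoter_fraction = if (is.null(acrs)) NA_real_
      else mean(acrs$acr_class == "promoter"),
    n_clusters = if (is.null(clusters)) NA_integer_ else nrow(clusters),
    n_ses = n_ses,
    se_length_threshold = se_length_threshold,
    mean_se_length = mean(lens),
    se_length_range = range(lens),
    mean_constituents = if ("n_constituents" %in% names(ses))
      mean(ses$n_constituents) else NA_real_,
    n_genic = n_genic,
    n_intergenic = n_intergenic,
    genic_percent = round(100 * n_genic / n_ses),
    fraction_near_gene_end = frac_near,
    near_end_bp = near_end_bp)
  class(out) <- "atlas_summary"
  out
}

#' @export
print.atlas_summary <- function(x, ...) {
  cat("ACR/SE atlas summary\n")
  if (!is.na(x$n_acrs))
    cat(sprintf("  ACRs: %d (%.0f%% promoter)\n", x$n_acrs,
                100 * x$promoter_fraction))
  if (!is.na(x$n_clusters)) cat("  nonpromoter clusters:", x$n_clusters, "\n")
  cat(sprintf("  SEs: %d (length threshold %s bp, mean %.0f bp, range %d-%d)\n",
              x$n_ses, format(x$se_length_threshold), x$mean_se_length,
              x$se_length_range[1], x$se_length_range[2]))
  cat(sprintf("  genic: %d (%d%%), intergenic: %d\n", x$n_genic,
              x$genic_percent, x$n_intergenic))
  invisible(x)
}
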