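#' Gene density in sliding windows with region-length correction
#'
#' The genome is tiled with `window_bp` windows advancing by `step_bp`.
#' Per window, `n_genes` counts genes whose body overlaps the window by at
#' least 1 bp, `subtracted_length` is the total bp of `subtract_regions`
#' (pre-merged; typically the SE set) inside the window, and
#' `density = window_bp * n_genes / (window_bp - subtracted_length)`:
#' genes per effective window after discounting the subtracted regions.
#' Windows fully covered by subtracted regions get `NA` density and are
#' flagged. Only full-length windows are emitted.
#'
#' @param gm a [gene_models()] object.
#' @param genome a [genome_index()] (chromosome lengths).
#' @param subtract_regions interval table (or NULL for none).
#' @param window_bp window size, bp (default 15000).
#' @param step_bp step, bp (default 5000).
#' @return data.frame: `chrom`, `start`, `end`, `n_genes`,
#'   `subtracted_length`, `density`, `undefined`.
#' @export
gene_density_windows <- function(gm, genome, subtract_regions = NULL,
                                 window_bp = 15000L, step_bp = 5000L) {
  wins <- do.call(rbind, lapply(names(genome$seqlengths), function(ch) {
    L <- genome$seqlengths[[ch]]
    if (L < window_bp) return(NULL)
    s <- seq(0L, L - window_bp, by = step_bp)
    data.frame(chrom = ch, start = s, end = s + as.integer(window_bp),
               stringsAsFactors = FALSE)
  }))
  if (is.null(wins)) stop("no chromosome is at least one window long")
  gb <- gm$genes[, c("chrom", "start", "end")]
  hits <- GenomicRanges::countOverlaps(as_granges(wins), as_granges(gb),
                                       ignore.strand = TRUE)
  wins$n_genes <- as.integer(hits)
  if (is.null(subtract_regions) || nrow(subtract_regions) == 0) {
    wins$subtracted_length <- 0L
  } else {
    sub <- merge_intervals(subtract_regions, max_gap = 0L)
    wins$subtracted_length <- covered_bp(wins, sub)
  }
  wins$undefined <- wins$subtracted_length >= window_bp
  wins$density <- ifelse(wins$undefined, NA_real_,
                         window_bp * wins$n_genes /
                           (window_bp - wins$subtracted_length))
  wins
}

#' Fraction of regions located within TADs
#'
#' @param regions interval table.
#' @param tads interval table of TAD spans.
#' @param rule `"containment"` (default): a region counts iff it is fully
#'   contained in at least one TAD; `"overlap"`: iff at least
#'   `min_overlap_frac` of the region overlaps the TAD union.
#' @param min_overlap_frac fractional-overlap threshold for the overlap
#'   rule.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_within_tads <- function(regions, tads, rule = c("containment", "overlap"),
                                 min_overlap_frac = 0.5) {
  rule <- match.arg(rule)
  if (nrow(regions) == 0) stop("empty region list")
  if (nrow(tads) == 0) return(0)
  if (rule == "containment") {
    hits <- GenomicRanges::findOverlaps(as_granges(regions), as_granges(tads),
                                        type = "within", ignore.strand = TRUE)
    mean(seq_len(nrow(regions)) %in% S4Vectors::queryHits(hits))
  } else {
    cov <- covered_bp(regions, tads)
    mean(cov >= min_overlap_frac * (regions$end - regions$start))
  }
}

#' Place size-matched random regions in nongenic space
#'
#' Draws `n_sets` independent sets, each containing one interval per entry
#' of `size_list`, placed uniformly at random (chromosome chosen
#' proportional to length) and rejected until it overlaps no gene body.
#'
#' @param genome a [genome_index()].
#' @param gm a [gene_models()] object.
#' @param size_list integer vector of region sizes, bp.
#' @param n_sets number of random sets.
#' @param seed integer seed.
#' @param max_tries rejections allowed per region before erroring.
#' @return List of `n_sets` interval tables.
#' @export
sample_random_nongenic <- function(genome, gm, size_list, n_sets = 1000L,
                                   seed = 1L, max_tries = 10000L) {
  chroms <- names(genome$seqlengths)
  lens <- as.numeric(genome$seqlengths)
  gstart <- split(gm$genes$start, gm$genes$chrom)
  gend <- split(gm$genes$end, gm$genes$chrom)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      chrom <- character(length(size_list))
      start <- integer(length(size_list))
      for (j in seq_along(size_list)) {
        size <- size_list[j]
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          ok_chr <- lens >= size
          ci <- sample.int(length(chroms), 1, prob = ifelse(ok_chr, lens, 0))
          st <- sample.int(as.integer(lens[ci] - size + 1), 1) - 1L
          gs <- gstart[[chroms[ci]]]
          if (is.null(gs) || !any(st < gend[[chroms[ci]]] & st + size > gs)) {
            placed <- TRUE
            chrom[j] <- chroms[ci]; start[j] <- st
            break
          }
        }
        if (!placed)
          stop("could not place nongenic region of size ", size,
               " after ", max_tries, " tries")
      }
      data.frame(chrom = chrom, start = start,
                 end = start + as.integer(size_list),
                 stringsAsFactors = FALSE)
    })
  })
}

#' Empirical enrichment test against resampled null fractions
#'
#' Add-one empirical p-value:
#' `p = (1 + #{null >= observed}) / (1 + n_sets)` for
#' `alternative = "greater"` (mirrored with `<=` for `"less"`), so p is
#' never 0 and lies in `(0, 1]`.
#'
#' @param observed_fraction observed statistic.
#' @param null_fractions numeric vector of null statistics.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List of class `enrichment_result`: `observed_fraction`,
#'   `null_fractions`, `p_value`, `n_sets`.
#' @export
empirical_enrichment_test <- function(observed_fraction, null_fractions,
                                      alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(null_fractions) < 1) stop("need at least one null value")
  extreme <- if (alternative == "greater")
    sum(null_fractions >= observed_fraction)
  else sum(null_fractions <= observed_fraction)
  out <- list(observed_fraction = observed_fraction,
              null_fractions = null_fractions,
              p_value = (1 + extreme) / (1 + length(null_fractions)),
              n_sets = length(null_fractions),
              alternative = alternative)
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("empirical enrichment: observed %.4f, p = %.4g (%s, %d null sets)\n",
              x$observed_fraction, x$p_value, x$alternative, x$n_sets))
  invisible(x)
}

#' Filter chromatin loops by FDR and link SEs to genes
#'
#' Keeps loops with `fdr < fdr_max` and emits one `(se_id, gene_id,
#' statistic)` row whenever one anchor overlaps the SE span and the other
#' overlaps the gene body or its promoter window.
#'
#' @param loops data.frame: `chrom`, `a1_start`, `a1_end`, `a2_start`,
#'   `a2_end`, `stat`, `fdr`.
#' @param ses SE table with `se_id`.
#' @param gm a [gene_models()] object.
#' @param fdr_max loop FDR ceiling (default 1e-10).
#' @param promoter_bp promoter window used on the gene side.
#' @return data.frame `se_id`, `gene_id`, `statistic`.
#' @export
filter_and_link_loops <- function(loops, ses, gm, fdr_max = 1e-10,
                                  promoter_bp = 500L) {
  need <- c("chrom", "a1_start", "a1_end", "a2_start", "a2_end", "stat", "fdr")
  miss <- setdiff(need, names(loops))
  if (length(miss)) stop("loop table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(loops$fdr) | loops$fdr < 0 | loops$fdr > 1 |
                 loops$a1_end <= loops$a1_start | loops$a2_end <= loops$a2_start)
  if (length(bad)) stop("malformed loop row at line ", bad[1])
  keep <- loops[loops$fdr < fdr_max, , drop = FALSE]
  out <- data.frame(se_id = character(), gene_id = character(),
                    statistic = numeric(), stringsAsFactors = FALSE)
  if (nrow(keep) == 0) return(out)
  gene_side <- rbind(
    data.frame(gm$genes[, c("chrom", "start", "end")],
               gene_id = gm$genes$gene_id),
    {
      pw <- promoter_windows(gm, promoter_bp)
      data.frame(pw[, c("chrom", "start", "end")], gene_id = pw$gene_id)
    })
  rows <- list()
  for (i in seq_len(nrow(keep))) {
    a1 <- data.frame(chrom = keep$chrom[i], start = keep$a1_start[i],
                     end = keep$a1_end[i])
    a2 <- data.frame(chrom = keep$chrom[i], start = keep$a2_start[i],
                     end = keep$a2_end[i])
    for (ord in list(c(1, 2), c(2, 1))) {
      se_anchor <- list(a1, a2)[[ord[1]]]
      g_anchor <- list(a1, a2)[[ord[2]]]
      se_hit <- overlaps_any(ses, se_anchor)
      g_hit <- overlaps_any(gene_side, g_anchor)
      if (any(se_hit) && any(g_hit)) {
        rows[[length(rows) + 1]] <- expand.grid(
          se_id = ses$se_id[se_hit],
          gene_id = unique(gene_side$gene_id[g_hit]),
          statistic = keep$stat[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' One-sided rank-sum comparison of two gene sets across tissues
#'
#' Tests whether expression of `genes_a` is stochastically greater than
#' `genes_b` in each tissue. For combined sample sizes up to
#' `exact_max_n` the p-value is computed by exhaustive enumeration of all
#' group assignments of the observed values (a permutation Mann-Whitney
#' test, valid under ties); larger samples use the normal approximation
#' with tie correction.
#'
#' @param expr matrix or data.frame, genes x tissues, rownames = gene ids.
#' @param genes_a,genes_b character vectors of gene ids present in `expr`.
#' @param exact_max_n largest combined n for exact enumeration (default 12).
#' @return data.frame `tissue`, `p_value`, `all_tied`.
#' @export
compare_cognate_expression <- function(expr, genes_a, genes_b,
                                       exact_max_n = 12L) {
  expr <- as.matrix(expr)
  a <- intersect(genes_a, rownames(expr))
  b <- intersect(genes_b, rownames(expr))
  if (length(a) == 0 || length(b) == 0)
    stop("both gene sets must be non-empty and present in the matrix")
  res <- lapply(colnames(expr), function(ti) {
    va <- expr[a, ti]; vb <- expr[b, ti]
    if (length(unique(c(va, vb))) == 1L) {
      return(data.frame(tissue = ti, p_value = 1, all_tied = TRUE))
    }
    p <- if (length(va) + length(vb) <= exact_max_n)
      rank_sum_exact_p(va, vb)
    else stats::wilcox.test(va, vb, alternative = "greater",
                            exact = FALSE, correct = TRUE)$p.value
    data.frame(tissue = ti, p_value = p, all_tied = FALSE)
  })
  do.call(rbind, res)
}

# exact one-sided Mann-Whitney by enumeration of all assignments of the
# combined observed values to group a; ties handled naturally (U counts
# 0.5 per tied pair); p = P(U_perm >= U_obs)
rank_sum_exact_p <- function(a, b) {
  u_stat <- function(x, y) {
    sum(vapply(x, function(v) sum(v > y) + 0.5 * sum(v == y), numeric(1)))
  }
  comb <- c(a, b)
  n <- length(a)
  u_obs <- u_stat(a, b)
  sets <- utils::combn(length(comb), n)
  us <- apply(sets, 2, function(ix) u_stat(comb[ix], comb[-ix]))
  mean(us >= u_obs - 1e-9)
}
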