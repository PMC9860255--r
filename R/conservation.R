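#' Genes flanking each intergenic SE
#'
#' For every intergenic SE, finds the nearest gene on each side of the span
#' on the same chromosome (by construction no gene intervenes). Genic SEs
#' and SEs at a chromosome end are skipped with a reason.
#'
#' @param ses SE table with `se_id` and (optionally) `position_class`.
#' @param gm a [gene_models()] object.
#' @return data.frame: `se_id`, `upstream_gene`, `downstream_gene`,
#'   `skipped`, `reason`. "Upstream" is the left (lower-coordinate) flank.
#' @export
se_spanning_pairs <- function(ses, gm) {
  g <- gm$genes
  rows <- lapply(seq_len(nrow(ses)), function(i) {
    se <- ses[i, ]
    base <- data.frame(se_id = se$se_id, upstream_gene = NA_character_,
                       downstream_gene = NA_character_, skipped = TRUE,
                       reason = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(se$position_class) && !is.na(se$position_class) &&
        grepl("^genic", se$position_class)) {
      base$reason <- "genic"
      return(base)
    }
    cand <- g[g$chrom == se$chrom, , drop = FALSE]
    left <- cand[cand$end <= se$start, , drop = FALSE]
    right <- cand[cand$start >= se$end, , drop = FALSE]
    if (nrow(left) == 0 || nrow(right) == 0) {
      base$reason <- "chromosome_end"
      return(base)
    }
    base$upstream_gene <- left$gene_id[which.max(left$end)]
    base$downstream_gene <- right$gene_id[which.min(right$start)]
    base$skipped <- FALSE
    base
  })
  do.call(rbind, rows)
}

#' Per-species synteny status of SE-spanning gene pairs
#'
#' A pair is `syntenic_adjacent` in a species iff both flanking genes have
#' synteny partners there and the partners are adjacent in the target
#' annotation (no gene between them on the same chromosome);
#' `syntenic_nonadjacent` if both partners exist but are not adjacent;
#' `absent` otherwise.
#'
#' @param pairs output of [se_spanning_pairs()] (skipped rows are dropped).
#' @param synteny data.frame: `species`, `query_gene`, `target_gene`,
#'   `block_id`.
#' @param target_annotations named list (by species) of [gene_models()].
#' @return Long data.frame: `se_id`, `species`, `status`.
#' @export
syntenic_status <- function(pairs, synteny, target_annotations) {
  pairs <- pairs[!pairs$skipped, , drop = FALSE]
  species <- names(target_annotations)
  if (is.null(species)) stop("target_annotations must be named by species")
  unresolved <- setdiff(synteny$target_gene,
                        unlist(lapply(target_annotations,
                                      function(a) a$genes$gene_id)))
  # gene order rank per species chromosome for adjacency checks
  ranks <- lapply(target_annotations, function(a) {
    g <- a$genes[order(a$genes$chrom, a$genes$start), ]
    g$rank <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along)
    g
  })
  rows <- lapply(species, function(sp) {
    syn <- synteny[synteny$species == sp, , drop = FALSE]
    gsp <- ranks[[sp]]
    status <- vapply(seq_len(nrow(pairs)), function(i) {
      p1 <- syn$target_gene[syn$query_gene == pairs$upstream_gene[i]]
      p2 <- syn$target_gene[syn$query_gene == pairs$downstream_gene[i]]
      if (length(p1) == 0 || length(p2) == 0) return("absent")
      for (t1 in p1) for (t2 in p2) {
        r1 <- gsp[gsp$gene_id == t1, , drop = FALSE]
        r2 <- gsp[gsp$gene_id == t2, , drop = FALSE]
        if (nrow(r1) == 0)
          stop("unresolvable target gene id: ", t1, " (", sp, ")")
        if (nrow(r2) == 0)
          stop("unresolvable target gene id: ", t2, " (", sp, ")")
        if (r1$chrom == r2$chrom && abs(r1$rank - r2$rank) == 1L)
          return("syntenic_adjacent")
      }
      "syntenic_nonadjacent"
    }, character(1))
    data.frame(se_id = pairs$se_id, species = sp, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# scoring matrix: match +1, mismatch -1, N never matches anything
sw_submat <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 5, 5,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

#' Iterated masked local alignment of a query against a target
#'
#' Smith-Waterman local alignment with affine gaps (a gap of length L
#' costs `gap_open + L * gap_extend`), both target strands searched. After
#' each hit is reported its query region is masked with N (which never
#' matches) and the next-best query-non-overlapping hit is extracted, until
#' the raw score drops below `min_score`. Hits shorter than `min_hit_len`
#' aligned columns or below `min_identity` (matches / aligned columns) are
#' discarded but still masked.
#'
#' @param query,target character or DNAString sequences over A/C/G/T/N.
#' @param match,mismatch,gap_open,gap_extend scoring (penalties positive).
#' @param min_identity minimum hit identity (default 0.70).
#' @param min_hit_len minimum aligned columns per hit (default 30).
#' @param min_score stop extracting below this raw score (default 30, the
#'   conventional minimum local-alignment score; random-sequence best local
#'   scores at these parameters sit near 10-12, so 30 excludes chance
#'   hits).
#' @param max_hits iteration cap.
#' @return data.frame of accepted hits: `q_start`, `q_end`, `t_start`,
#'   `t_end` (0-based half-open; target in forward coordinates), `strand`,
#'   `score`, `matches`, `columns`, `identity`.
#' @export
local_align <- function(query, target, match = 1, mismatch = -1,
                        gap_open = 2, gap_extend = 1, min_identity = 0.70,
                        min_hit_len = 30, min_score = 30, max_hits = 50) {
  qs <- toupper(as.character(query))
  ts <- toupper(as.character(target))
  if (nchar(qs) == 0 || nchar(ts) == 0) stop("empty sequence")
  submat <- sw_submat(match, mismatch)
  tgt_f <- Biostrings::DNAString(ts)
  tgt_r <- Biostrings::reverseComplement(tgt_f)
  t_len <- nchar(ts)
  qcur <- qs
  hits <- list()
  for (iter in seq_len(max_hits)) {
    qd <- Biostrings::DNAString(qcur)
    af <- Biostrings::pairwiseAlignment(qd, tgt_f, type = "local",
                                        substitutionMatrix = submat,
                                        gapOpening = gap_open,
                                        gapExtension = gap_extend)
    ar <- Biostrings::pairwiseAlignment(qd, tgt_r, type = "local",
                                        substitutionMatrix = submat,
                                        gapOpening = gap_open,
                                        gapExtension = gap_extend)
    fwd <- Biostrings::score(af) >= Biostrings::score(ar)
    aln <- if (fwd) af else ar
    sc <- Biostrings::score(aln)
    if (sc < min_score) break
    pq <- Biostrings::pattern(aln)
    pt <- Biostrings::subject(aln)
    q1 <- Biostrings::start(pq); q2 <- Biostrings::end(pq)
    t1 <- Biostrings::start(pt); t2 <- Biostrings::end(pt)
    columns <- nchar(as.character(pq))
    matches <- Biostrings::nmatch(aln)
    identity <- matches / columns
    if (!fwd) {  # map reverse-strand coordinates back to forward target
      tmp <- c(t_len - t2, t_len - t1 + 1L)
      t1 <- tmp[1] + 1L; t2 <- tmp[2]
    }
    if (columns >= min_hit_len && identity >= min_identity) {
      hits[[length(hits) + 1]] <- data.frame(
        q_start = q1 - 1L, q_end = q2, t_start = t1 - 1L, t_end = t2,
        strand = if (fwd) "+" else "-", score = sc,
        matches = matches, columns = columns, identity = identity)
    }
    # mask the reported query region and continue
    substr(qcur, q1, q2) <- strrep("N", q2 - q1 + 1L)
  }
  if (length(hits) == 0) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      t_start = integer(), t_end = integer(),
                      strand = character(), score = numeric(),
                      matches = integer(), columns = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(-out$score), , drop = FALSE]
}

#' Search a target intergenic sequence for the ortholog of an SE
#'
#' Runs [local_align()] and summarizes the accepted hits:
#' `aligned_fraction` = 100 x (query bp covered by hits, union) / SE
#' length; `identity` = 100 x total matches / total aligned columns.
#'
#' @param se_seq SE sequence (query).
#' @param target_seq intergenic sequence between the syntenic gene partners.
#' @param ... passed to [local_align()].
#' @return List (`aligned_fraction`, `identity`, `hits`) or `NULL` when no
#'   hit is accepted.
#' @export
ortholog_se_search <- function(se_seq, target_seq, ...) {
  hits <- local_align(se_seq, target_seq, ...)
  if (nrow(hits) == 0) return(NULL)
  qlen <- nchar(as.character(se_seq))
  cov <- sum(hits$q_end - hits$q_start)  # masked iteration => disjoint in query
  list(aligned_fraction = 100 * cov / qlen,
       identity = 100 * sum(hits$matches) / sum(hits$columns),
       hits = hits)
}

#' TF motif retention rate in an orthologous sequence
#'
#' A query motif is retained iff at least one hit with the same motif id
#' occurs within the orthologous aligned target regions (presence, not
#' positional conservation).
#'
#' @param query_motifs character vector (or data.frame with `motif_id`) of
#'   motifs found in the query SE.
#' @param ortholog_motifs same, for the orthologous target regions.
#' @return List: `n_motifs_query`, `n_retained`, `retention_rate` (percent;
#'   `NA` with `undefined = TRUE` when there are no query motifs).
#' @export
motif_retention <- function(query_motifs, ortholog_motifs) {
  ids <- function(x) if (is.data.frame(x)) unique(x$motif_id) else unique(x)
  q <- ids(query_motifs); o <- ids(ortholog_motifs)
  if (length(q) == 0) {
    return(list(n_motifs_query = 0L, n_retained = 0L,
                retention_rate = NA_real_, undefined = TRUE))
  }
  kept <- sum(q %in% o)
  list(n_motifs_query = length(q), n_retained = kept,
       retention_rate = 100 * kept / length(q), undefined = FALSE)
}

#' Cross-species conservation report
#'
#' @param status long data.frame from [syntenic_status()].
#' @param ortho_hits data.frame: `se_id`, `species`, `aligned_fraction`,
#'   `identity` (one row per SE with an accepted ortholog hit).
#' @param ses SE table (for CNS containment).
#' @param cns interval table of conserved noncoding sequences, or NULL.
#' @return List with `per_species` (n_syntenic, n_hit, percent_hit rounded
#'   and unrounded, mean identity/aligned fraction), `n_se_any_pair` (SEs
#'   syntenic in >= 1 species), and CNS containment counts/percentages.
#' @export
conservation_report <- function(status, ortho_hits, ses = NULL, cns = NULL) {
  sp <- sort(unique(status$species))
  per <- lapply(sp, function(s) {
    st <- status[status$species == s, , drop = FALSE]
    syn <- st$se_id[st$status == "syntenic_adjacent"]
    oh <- ortho_hits[ortho_hits$species == s &
                       ortho_hits$se_id %in% syn, , drop = FALSE]
    n_syn <- length(unique(syn))
    n_hit <- length(unique(oh$se_id))
    data.frame(species = s, n_syntenic = n_syn, n_hit = n_hit,
               percent_hit = if (n_syn > 0) round(100 * n_hit / n_syn) else NA_real_,
               percent_hit_raw = if (n_syn > 0) 100 * n_hit / n_syn else NA_real_,
               mean_identity = if (nrow(oh)) mean(oh$identity) else NA_real_,
               mean_aligned_fraction = if (nrow(oh)) mean(oh$aligned_fraction)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  any_pair <- unique(status$se_id[status$status == "syntenic_adjacent"])
  out <- list(per_species = per, n_se_any_pair = length(any_pair))
  if (!is.null(ses) && !is.null(cns)) {
    sub <- ses[ses$se_id %in% any_pair, , drop = FALSE]
    n_cns <- if (nrow(sub)) sum(overlaps_any(sub, cns)) else 0L
    out$n_se_with_cns <- n_cns
    out$percent_cns <- if (length(any_pair) > 0)
      round(100 * n_cns / length(any_pair)) else NA_real_
    out$percent_cns_raw <- if (length(any_pair) > 0)
      100 * n_cns / length(any_pair) else NA_real_
  }
  out
}

#' Synteny maintenance of SE-spanning pairs versus a background pool
#'
#' A pair "maintains synteny" in a species iff its status there is
#' `syntenic_adjacent`. The statistic is the percentage of pairs
#' maintaining synteny in at least `min_species` of the species analyzed.
#' The null distribution resamples `length(with_se)` pairs (without
#' replacement) from the without-SE pool `n_resamples` times; the add-one
#' empirical p-value tests whether the with-SE percentage is greater.
#'
#' @param with_se integer vector: per SE-spanning pair, the number of
#'   species in which it is syntenic_adjacent.
#' @param without_se same, for the background pool of gene pairs.
#' @param min_species threshold on the species count (default 5).
#' @param n_resamples null resamples (default 1000).
#' @param seed integer seed.
#' @return List: `percent_with`, `percent_without`, `p_value`, `capped`
#'   (TRUE when the pool was smaller than the draw size).
#' @export
synteny_maintenance <- function(with_se, without_se, min_species = 5L,
                                n_resamples = 1000L, seed = 1L) {
  maintain <- function(x) 100 * mean(x >= min_species)
  pw <- maintain(with_se)
  pwo <- maintain(without_se)
  draw <- length(with_se)
  capped <- draw > length(without_se)
  if (capped) draw <- length(without_se)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_resamples),
           function(i) maintain(sample(without_se, draw, replace = FALSE)),
           numeric(1))
  })
  res <- empirical_enrichment_test(pw, nulls, alternative = "greater")
  list(percent_with = pw, percent_without = pwo, p_value = res$p_value,
       n_with = length(with_se), n_without = length(without_se),
       n_resamples = as.integer(n_resamples), capped = capped)
}
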