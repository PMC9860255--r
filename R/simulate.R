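#' Configuration for the synthetic study generator
#'
#' Defaults emulate the scale and structure of a plant accessible-chromatin
#' SE study shrunk to desk size: a 2 x 1 Mb genome with 300 genes, 6
#' DNase-seq-like samples, 20 planted intergenic SE clusters (3-8
#' constituents of ~400 bp separated by < 50 bp gaps, total span > 1.5 kb)
#' over 400 background nonpromoter ACRs (~395 bp mean, well separated so
#' they stay singletons), promoter peaks at 500-bp TSS-upstream windows,
#' TAD-like domains covering 25% of the genome with planted SEs contained
#' at twice the baseline rate, one TF enriched at constituents, a
#' five-species ortholog panel on a substitution-rate ladder with synteny
#' breaks, planted literal 8-mer motif words, and junction read-pair
#' libraries for known insertion loci.
#'
#' @param seed integer master seed.
#' @param ... overrides for any default field (see source for the full
#'   list).
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = 2L, chrom_length = 1000000L,
    n_genes = 300L,
    gene_len_meanlog = log(2000), gene_len_sdlog = 0.35,
    gene_min_gap = 1000L,
    n_samples = 6L,
    n_planted_ses = 20L,
    constituents_range = c(3L, 8L),
    constituent_len_mean = 400, constituent_len_sd = 80,
    intra_gap_range = c(20L, 45L),
    min_planted_se_length = 1600L,
    n_background_acrs = 400L,
    background_len_meanlog = log(370), background_len_sdlog = 0.35,
    promoter_peak_prob = 0.6,
    sample_support_prob = 0.7,
    read_depth_per_peak = 40L,
    background_read_rate = 0.002,   # reads per bp per sample
    promoter_upstream = 500L,
    tad_coverage = 0.25, tad_enrichment = 2.0,
    tad_len_mean = 10000, tad_len_sd = 2000,
    n_decoy_loops = 30L,
    n_tfs = 12L,
    tf_rate_constituent = 0.8, tf_rate_other = 0.2,
    tf_rate_enriched_other = 0.1,
    expr_mean = 3, expr_sd = 1, se_cognate_shift = 2,
    n_motif_vocab = 10L, motifs_per_se = 4L, motif_len = 8L,
    species_divergence = c(aly = 0.05, bst = 0.12, cru = 0.20,
                           aal = 0.30, bra = 0.40),
    indel_rate = 0.002,
    synteny_break_prob = 0.15,
    background_break_prob = 0.35,
    maintenance_min_species = 4L,
    n_insertion_loci = 6L,
    insertion_element_len = 1100L,
    junction_flank = 200L,
    pairs_per_junction = 12L,
    read_len = 50L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome and gene annotation
#'
#' I.i.d. uniform A/C/G/T chromosomes; genes placed left to right without
#' overlap with random inter-gene gaps (at least `gene_min_gap` bp), random
#' strands, and 1-5 exons partitioning the body with >= 50 bp exons and
#' introns.
#'
#' @param config a [simulation_config()].
#' @return List with `genome` (a [genome_index()] with sequence), `genes`
#'   (a [gene_models()]), and `truth` (gene table).
#' @export
simulate_genome_and_annotation <- function(config) {
  with_seed(config$seed + 101L, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    seqs <- vapply(chroms, function(ch) random_dna(config$chrom_length),
                   character(1))
    per_chrom <- diff(round(seq(0, config$n_genes,
                                length.out = config$n_chromosomes + 1L)))
    gene_rows <- list(); exon_rows <- list()
    gid <- 0L
    for (ci in seq_along(chroms)) {
      n <- per_chrom[ci]
      if (n == 0) next
      L <- config$chrom_length
      lens <- pmin(8000L, pmax(500L, round(stats::rlnorm(
        n, config$gene_len_meanlog, config$gene_len_sdlog))))
      free <- L - sum(lens) - (n + 1L) * config$gene_min_gap
      if (free <= 0) stop("genes cannot be placed without overlap; lower n_genes")
      w <- stats::rexp(n + 1L); w <- w / sum(w)
      gaps <- config$gene_min_gap + floor(free * w)
      starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n]))
      for (k in seq_len(n)) {
        gid <- gid + 1L
        id <- sprintf("G%04d", gid)
        s <- as.integer(starts[k]); e <- s + lens[k]
        strand <- sample(c("+", "-"), 1)
        gene_rows[[gid]] <- data.frame(gene_id = id, chrom = chroms[ci],
                                       start = s, end = e, strand = strand,
                                       stringsAsFactors = FALSE)
        n_ex <- sample.int(5L, 1L)
        n_parts <- 2L * n_ex - 1L
        if (n_parts == 1L) {
          bounds <- c(s, e)
        } else {
          pw <- stats::rexp(n_parts); pw <- pw / sum(pw)
          plen <- pmax(50L, floor((lens[k] - n_parts * 50L) * pw) + 50L)
          plen[n_parts] <- lens[k] - sum(plen[-n_parts])
          bounds <- s + cumsum(c(0L, plen))
        }
        ex_idx <- seq(1L, n_parts, by = 2L)
        exon_rows[[gid]] <- data.frame(
          gene_id = id, chrom = chroms[ci],
          start = as.integer(bounds[ex_idx]),
          end = as.integer(bounds[ex_idx + 1L]), stringsAsFactors = FALSE)
      }
    }
    genes_df <- if (gid > 0) do.call(rbind, gene_rows)
    else data.frame(gene_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    stringsAsFactors = FALSE)
    exons_df <- if (gid > 0) do.call(rbind, exon_rows) else NULL
    gm <- gene_models(genes_df, exons_df)
    genome <- list(seqlengths = stats::setNames(
      rep(config$chrom_length, length(chroms)), chroms),
      sequences = Biostrings::DNAStringSet(seqs))
    class(genome) <- "genome_index"
    list(genome = genome, genes = gm, truth = list(genes = gm$genes))
  })
}

# non-overlapping random placement helper: sample a start for an interval of
# `size` on `chrom` of length `L` such that [start, start+size) stays
# `clearance` away from every interval in `avoid` (same chrom, pre-filtered)
place_clear <- function(L, size, avoid_start, avoid_end, clearance,
                        max_tries = 2000L) {
  for (i in seq_len(max_tries)) {
    st <- sample.int(L - size, 1L)
    if (!length(avoid_start) ||
        all(st >= avoid_end + clearance | st + size <= avoid_start - clearance))
      return(st)
  }
  NA_integer_
}

#' Plant the multi-sample accessibility landscape
#'
#' Plants intergenic SE clusters (constituents with < 50 bp gaps, each
#' supported by a random subset of samples), background nonpromoter ACRs
#' kept >= 200 bp from SEs, >= ~550 bp from gene bodies (clear of promoter
#' windows) and far enough apart not to chain, and per-sample promoter
#' peaks. Per-sample read-start tracks draw `read_depth_per_peak` reads
#' around each supported peak center (normal, sd = length/4) over a uniform
#' background.
#'
#' @param config a [simulation_config()].
#' @param ann output of [simulate_genome_and_annotation()].
#' @return List with `sample_peaks` (named list of per-sample peak tables),
#'   `tracks` (per sample, per chromosome [read_start_track()]s), and
#'   `truth` (planted SEs, constituents, per-site class table).
#' @export
plant_accessibility_landscape <- function(config, ann) {
  gm <- ann$genes
  g <- gm$genes
  chroms <- names(ann$genome$seqlengths)
  with_seed(config$seed + 202L, {
    # --- candidate intergenic gaps (clear of promoter windows by 720 bp)
    gaps <- do.call(rbind, lapply(chroms, function(ch) {
      gg <- g[g$chrom == ch, ]
      gg <- gg[order(gg$start), ]
      if (nrow(gg) < 2) return(NULL)
      data.frame(chrom = ch, lo = gg$end[-nrow(gg)] + 720L,
                 hi = gg$start[-1] - 720L, stringsAsFactors = FALSE)
    }))
    gaps <- gaps[gaps$hi - gaps$lo > 0, ]
    # --- planted SEs
    se_rows <- list(); con_rows <- list()
    widths <- gaps$hi - gaps$lo
    for (k in seq_len(config$n_planted_ses)) {
      repeat {
        n_c <- sample(seq(config$constituents_range[1],
                          config$constituents_range[2]), 1L)
        lens <- pmax(150L, pmin(800L, round(stats::rnorm(
          n_c, config$constituent_len_mean, config$constituent_len_sd))))
        cgaps <- sample(seq(config$intra_gap_range[1],
                            config$intra_gap_range[2]), n_c - 1L,
                        replace = TRUE)
        total <- sum(lens) + sum(cgaps)
        if (total >= config$min_planted_se_length) break
      }
      ok <- which(widths >= total)
      if (!length(ok)) stop("insufficient intergenic space for planted SE")
      gi <- sample(ok, 1L, prob = widths[ok])
      st <- gaps$lo[gi] + sample.int(widths[gi] - total + 1L, 1L) - 1L
      cs <- st + cumsum(c(0L, lens[-n_c] + cgaps))
      con_rows[[k]] <- data.frame(chrom = gaps$chrom[gi], start = cs,
                                  end = cs + lens,
                                  se_truth = sprintf("TSE%02d", k),
                                  stringsAsFactors = FALSE)
      se_rows[[k]] <- data.frame(chrom = gaps$chrom[gi], start = st,
                                 end = st + total,
                                 se_truth = sprintf("TSE%02d", k),
                                 n_constituents = n_c,
                                 stringsAsFactors = FALSE)
      # retire the whole gene gap: one SE per flanking gene pair keeps the
      # spanning-pair truth unambiguous
      gaps <- gaps[-gi, , drop = FALSE]
      widths <- gaps$hi - gaps$lo
    }
    se_truth <- do.call(rbind, se_rows)
    con_truth <- do.call(rbind, con_rows)
    # --- background ACRs
    avoid <- rbind(
      data.frame(chrom = g$chrom, start = g$start - 550L, end = g$end + 550L),
      data.frame(chrom = se_truth$chrom, start = se_truth$start - 200L,
                 end = se_truth$end + 200L))
    n_bg <- config$n_background_acrs
    bg_list <- list()
    lens_bg <- pmax(100L, pmin(1200L, round(stats::rlnorm(
      n_bg, config$background_len_meanlog, config$background_len_sdlog))))
    for (k in seq_len(n_bg)) {
      ch <- sample(chroms, 1L)
      av <- avoid[avoid$chrom == ch, ]
      st <- place_clear(config$chrom_length, lens_bg[k],
                        av$start, av$end, clearance = 0L)
      if (is.na(st)) stop("could not place background ACR")
      bg_list[[k]] <- data.frame(chrom = ch, start = st,
                                 end = st + lens_bg[k],
                                 stringsAsFactors = FALSE)
      # keep later background ACRs >= 60 bp away so singletons never chain
      avoid <- rbind(avoid, data.frame(chrom = ch, start = st - 60L,
                                       end = st + lens_bg[k] + 60L))
    }
    bg_truth <- do.call(rbind, bg_list)
    bg_truth$site_id <- sprintf("BG%04d", seq_len(nrow(bg_truth)))
    # --- promoter peak sites (one 400-bp peak inside each promoter window)
    pw <- promoter_windows(gm, config$promoter_upstream)
    off <- floor((config$promoter_upstream - 400L) / 2)
    prom_sites <- data.frame(chrom = pw$chrom, start = pw$start + off,
                             end = pw$start + off + 400L,
                             gene_id = pw$gene_id, stringsAsFactors = FALSE)
    # --- assemble site table with per-sample support
    samples <- sprintf("S%02d", seq_len(config$n_samples))
    support_mask <- function(n) {
      m <- matrix(stats::runif(n * config$n_samples) < config$sample_support_prob,
                  nrow = n)
      none <- rowSums(m) == 0
      m[cbind(which(none), sample.int(config$n_samples, sum(none),
                                      replace = TRUE))] <- TRUE
      m
    }
    sites <- rbind(
      data.frame(chrom = con_truth$chrom, start = con_truth$start,
                 end = con_truth$end, class = "constituent",
                 site_id = sprintf("CON%03d", seq_len(nrow(con_truth))),
                 stringsAsFactors = FALSE),
      data.frame(chrom = bg_truth$chrom, start = bg_truth$start,
                 end = bg_truth$end, class = "background",
                 site_id = bg_truth$site_id, stringsAsFactors = FALSE))
    m_site <- support_mask(nrow(sites))
    m_prom <- matrix(stats::runif(nrow(prom_sites) * config$n_samples) <
                       config$promoter_peak_prob, nrow = nrow(prom_sites))
    sample_peaks <- stats::setNames(lapply(seq_along(samples), function(si) {
      pk <- rbind(sites[m_site[, si], c("chrom", "start", "end")],
                  prom_sites[m_prom[, si], c("chrom", "start", "end")])
      pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
      rownames(pk) <- NULL
      pk$strand <- "*"
      pk
    }), samples)
    # --- read-start tracks
    tracks <- stats::setNames(lapply(seq_along(samples), function(si) {
      out <- list()
      for (ch in chroms) {
        pk <- sample_peaks[[si]]
        pk <- pk[pk$chrom == ch, ]
        reads <- integer(0)
        if (nrow(pk)) {
          centers <- rep((pk$start + pk$end) %/% 2L, each = config$read_depth_per_peak)
          sds <- rep((pk$end - pk$start) / 4, each = config$read_depth_per_peak)
          reads <- round(stats::rnorm(length(centers), centers, sds))
        }
        n_bgr <- round(config$background_read_rate * config$chrom_length)
        reads <- c(reads, sample.int(config$chrom_length, n_bgr,
                                     replace = TRUE) - 1L)
        reads <- pmin(pmax(as.integer(reads), 0L), config$chrom_length - 1L)
        out[[ch]] <- read_start_track(ch, reads, config$chrom_length)
      }
      out
    }), samples)
    # per-site class truth against the union atlas
    class_truth <- rbind(
      data.frame(chrom = sites$chrom, start = sites$start, end = sites$end,
                 class = "nonpromoter", site = sites$class,
                 stringsAsFactors = FALSE),
      data.frame(chrom = prom_sites$chrom, start = prom_sites$start,
                 end = prom_sites$end, class = "promoter", site = "promoter",
                 stringsAsFactors = FALSE))
    list(sample_peaks = sample_peaks, tracks = tracks,
         truth = list(ses = se_truth, constituents = con_truth,
                      background = bg_truth, sites = class_truth,
                      promoter_sites = prom_sites))
  })
}

# substitution + small indel mutator; returns the mutated string
mutate_sequence <- function(seq, sub_rate, indel_rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  subs <- which(stats::runif(n) < sub_rate)
  if (length(subs)) {
    ch[subs] <- vapply(ch[subs], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  if (indel_rate > 0) {
    ev <- which(stats::runif(n) < indel_rate)
    if (length(ev)) {
      keep <- rep(TRUE, n)
      ins <- vector("list", n)
      for (i in ev) {
        if (stats::runif(1) < 0.5) {          # deletion of 1-3 bases
          keep[i:min(n, i + sample.int(3L, 1L) - 1L)] <- FALSE
        } else {                               # insertion of 1-3 bases
          ins[[i]] <- sample(c("A", "C", "G", "T"), sample.int(3L, 1L),
                             replace = TRUE)
        }
      }
      res <- vector("list", n)
      for (i in seq_len(n)) {
        res[[i]] <- c(if (keep[i]) ch[i], ins[[i]])
      }
      ch <- unlist(res)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate TADs, loops, TF peaks, motif hits, and expression
#'
#' TAD-like domains (~10 kb) cover `tad_coverage` of the genome; exactly
#' `round(tad_enrichment * tad_coverage * n_planted_ses)` planted SEs are
#' placed fully inside a TAD and the rest are kept out (containment), so
#' the planted SE TAD-membership equals the design value. Loops connect
#' every planted SE to its cognate gene promoter at FDR < 1e-10, with
#' decoys above the cutoff. TF 1 binds constituents at
#' `tf_rate_constituent` and other classes at `tf_rate_enriched_other`;
#' remaining TFs bind every class at `tf_rate_other` (a bound ACR is fully
#' covered; some unbound ACRs get sub-threshold 30% peaks). Literal 8-mer
#' motif words are written into the genome inside each planted SE and
#' reported as motif hits. Expression is normal on the log scale with a
#' `se_cognate_shift` SD shift for SE-cognate genes.
#'
#' @param config a [simulation_config()].
#' @param ann output of [simulate_genome_and_annotation()] (genome is
#'   modified in place by motif planting and returned).
#' @param landscape output of [plant_accessibility_landscape()].
#' @return List: `tads`, `loops`, `tf_peaks`, `motif_hits`, `expression`,
#'   `genome` (with motif words), `truth` additions (`tad_membership`,
#'   `cognate`, `motif_vocab`, `enriched_tf`).
#' @export
simulate_context <- function(config, ann, landscape) {
  g <- ann$genes$genes
  se <- landscape$truth$ses
  chroms <- names(ann$genome$seqlengths)
  with_seed(config$seed + 303L, {
    # --- cognate truth: nearest gene per planted SE
    cognate <- vapply(seq_len(nrow(se)), function(i) {
      cand <- g[g$chrom == se$chrom[i], ]
      d <- pmax(cand$start - se$end[i], se$start[i] - cand$end, 0L)
      cand$gene_id[which.min(d)]
    }, character(1))
    # --- TADs
    n_in <- round(min(1, config$tad_enrichment * config$tad_coverage) * nrow(se))
    in_idx <- if (n_in > 0) sample.int(nrow(se), n_in) else integer(0)
    other_se <- function(i, st, en) {
      # would this TAD fully contain a planted SE it should not?
      out <- se[setdiff(seq_len(nrow(se)), c(i, in_idx)), , drop = FALSE]
      out <- out[out$chrom == se$chrom[i], , drop = FALSE]
      nrow(out) > 0 && any(out$start >= st & out$end <= en)
    }
    tad_rows <- list()
    for (i in in_idx) {
      se_len <- se$end[i] - se$start[i]
      for (try in 1:50) {
        tlen <- max(se_len + 2000L,
                    round(stats::rnorm(1, config$tad_len_mean, config$tad_len_sd)))
        off <- sample.int(tlen - se_len - 200L, 1L) + 100L
        st <- max(0L, se$start[i] - off)
        en <- min(config$chrom_length, st + tlen)
        if (!other_se(i, st, en)) break
      }
      tad_rows[[length(tad_rows) + 1]] <-
        data.frame(chrom = se$chrom[i], start = st, end = en,
                   stringsAsFactors = FALSE)
    }
    target_bp <- config$tad_coverage * config$n_chromosomes *
      as.numeric(config$chrom_length)
    cur <- if (length(tad_rows)) do.call(rbind, tad_rows)
    else data.frame(chrom = character(), start = integer(), end = integer())
    total <- sum(cur$end - cur$start)
    out_se <- se[-in_idx, , drop = FALSE]
    tries <- 0L
    while (total < target_bp && tries < 20000L) {
      tries <- tries + 1L
      tlen <- max(4000L, round(stats::rnorm(1, config$tad_len_mean,
                                            config$tad_len_sd)))
      ch <- sample(chroms, 1L)
      st <- sample.int(config$chrom_length - tlen, 1L)
      cand <- data.frame(chrom = ch, start = st, end = st + tlen)
      ex <- cur[cur$chrom == ch, ]
      if (nrow(ex) && any(st < ex$end & st + tlen > ex$start)) next
      osub <- out_se[out_se$chrom == ch, ]
      if (nrow(osub) && any(osub$start >= st & osub$end <= st + tlen)) next
      cur <- rbind(cur, cand)
      total <- total + tlen
    }
    tads <- cur[order(cur$chrom, cur$start), ]
    rownames(tads) <- NULL
    tad_membership <- data.frame(se_truth = se$se_truth,
                                 in_tad = seq_len(nrow(se)) %in% in_idx)
    # --- loops: each planted SE to its cognate promoter
    loop_rows <- lapply(seq_len(nrow(se)), function(i) {
      gi <- g[g$gene_id == cognate[i], ]
      mid_se <- (se$start[i] + se$end[i]) %/% 2L
      prom <- if (gi$strand == "+") gi$tss - 250L else gi$tss + 250L
      data.frame(chrom = se$chrom[i],
                 a1_start = mid_se - 1000L, a1_end = mid_se + 1000L,
                 a2_start = max(0L, prom - 1000L), a2_end = prom + 1000L,
                 stat = stats::runif(1, 10, 100),
                 fdr = 10^-stats::runif(1, 11, 14), stringsAsFactors = FALSE)
    })
    decoys <- lapply(seq_len(config$n_decoy_loops), function(i) {
      ch <- sample(chroms, 1L)
      a1 <- sample.int(config$chrom_length - 2000L, 1L)
      a2 <- sample.int(config$chrom_length - 2000L, 1L)
      data.frame(chrom = ch, a1_start = a1, a1_end = a1 + 2000L,
                 a2_start = a2, a2_end = a2 + 2000L,
                 stat = stats::runif(1, 1, 10),
                 fdr = 10^-stats::runif(1, 0, 9), stringsAsFactors = FALSE)
    })
    loops <- do.call(rbind, c(loop_rows, decoys))
    # --- TF peaks over planted site classes
    sites <- landscape$truth$sites
    tf_ids <- sprintf("TF%02d", seq_len(config$n_tfs))
    tf_peaks <- stats::setNames(lapply(seq_along(tf_ids), function(ti) {
      rate <- function(site_class) {
        if (ti == 1L) {
          if (site_class == "constituent") config$tf_rate_constituent
          else config$tf_rate_enriched_other
        } else config$tf_rate_other
      }
      rows <- lapply(seq_len(nrow(sites)), function(si) {
        r <- rate(sites$site[si])
        len <- sites$end[si] - sites$start[si]
        if (stats::runif(1) < r) {
          data.frame(chrom = sites$chrom[si], start = sites$start[si],
                     end = sites$end[si], stringsAsFactors = FALSE)
        } else if (stats::runif(1) < 0.1) {   # sub-threshold partial peak
          w <- max(10L, floor(0.3 * len))
          data.frame(chrom = sites$chrom[si], start = sites$start[si],
                     end = sites$start[si] + w, stringsAsFactors = FALSE)
        } else NULL
      })
      out <- do.call(rbind, rows)
      if (is.null(out)) data.frame(chrom = character(), start = integer(),
                                   end = integer())
      else out[order(out$chrom, out$start), , drop = FALSE]
    }), tf_ids)
    # --- plant literal motif words inside each SE and record hits
    vocab <- vapply(seq_len(config$n_motif_vocab), function(i)
      random_dna(config$motif_len), character(1))
    names(vocab) <- sprintf("M%02d", seq_len(config$n_motif_vocab))
    seqs <- as.character(ann$genome$sequences)
    hit_rows <- list()
    for (i in seq_len(nrow(se))) {
      picks <- sample(names(vocab), config$motifs_per_se)
      span <- se$end[i] - se$start[i] - config$motif_len
      offs <- sort(sample.int(span, config$motifs_per_se))
      # keep words non-overlapping
      offs <- offs + (seq_along(offs) - 1L) * config$motif_len
      offs <- offs[offs < span]
      picks <- picks[seq_along(offs)]
      for (j in seq_along(offs)) {
        p0 <- se$start[i] + offs[j]          # 0-based genome position
        substr(seqs[se$chrom[i]], p0 + 1L, p0 + config$motif_len) <-
          vocab[[picks[j]]]
        hit_rows[[length(hit_rows) + 1]] <- data.frame(
          motif_id = picks[j], chrom = se$chrom[i], start = p0,
          end = p0 + config$motif_len, se_truth = se$se_truth[i],
          stringsAsFactors = FALSE)
      }
    }
    genome <- ann$genome
    genome$sequences <- Biostrings::DNAStringSet(seqs)
    motif_hits <- do.call(rbind, hit_rows)
    # --- expression (log scale)
    tissues <- sprintf("T%02d", seq_len(config$n_samples))
    expr <- matrix(stats::rnorm(nrow(g) * length(tissues),
                                config$expr_mean, config$expr_sd),
                   nrow = nrow(g), dimnames = list(g$gene_id, tissues))
    expr[rownames(expr) %in% cognate, ] <-
      expr[rownames(expr) %in% cognate, ] +
      config$se_cognate_shift * config$expr_sd
    list(tads = tads, loops = loops, tf_peaks = tf_peaks,
         motif_hits = motif_hits, expression = expr, genome = genome,
         truth = list(tad_membership = tad_membership,
                      cognate = data.frame(se_truth = se$se_truth,
                                           gene_id = cognate),
                      motif_vocab = vocab, enriched_tf = "TF01"))
  })
}

#' Simulate the cross-species ortholog panel
#'
#' For each species the SE sequence is copied (with planted per-species
#' substitution and indel rates) between the target partners of its
#' flanking gene pair; synteny is broken with probability
#' `synteny_break_prob` per pair, half by dropping a partner from the
#' synteny table, half by inserting an extra gene between the partners in
#' the target annotation. Ortholog motif hits are regenerated by exact
#' string search for the planted motif words in the mutated sequences.
#'
#' @param config a [simulation_config()].
#' @param ann annotation as from [simulate_genome_and_annotation()].
#' @param landscape output of [plant_accessibility_landscape()].
#' @param context output of [simulate_context()] (motif-planted genome).
#' @return List: `synteny` (species/query_gene/target_gene/block_id),
#'   `target_annotations` (per-species [gene_models()]), `ortholog_seqs`
#'   (per species, named character vector keyed by planted SE id),
#'   `ortholog_motifs` (data.frame species/se_truth/motif_id), `truth`
#'   (per-pair per-species status and planted divergence).
#' @export
simulate_ortholog_panel <- function(config, ann, landscape, context) {
  g <- ann$genes$genes
  se <- landscape$truth$ses
  vocab <- context$truth$motif_vocab
  with_seed(config$seed + 404L, {
    # flanking pair truth for each planted SE
    pairs <- do.call(rbind, lapply(seq_len(nrow(se)), function(i) {
      cand <- g[g$chrom == se$chrom[i], ]
      left <- cand[cand$end <= se$start[i], ]
      right <- cand[cand$start >= se$end[i], ]
      data.frame(se_truth = se$se_truth[i],
                 up = left$gene_id[which.max(left$end)],
                 down = right$gene_id[which.min(right$start)],
                 stringsAsFactors = FALSE)
    }))
    # every consecutive gene pair, flagged when it spans a planted SE
    all_pairs <- do.call(rbind, lapply(unique(g$chrom), function(ci) {
      gg <- g[g$chrom == ci, ]
      gg <- gg[order(gg$start), ]
      if (nrow(gg) < 2) return(NULL)
      data.frame(up = gg$gene_id[-nrow(gg)], down = gg$gene_id[-1],
                 stringsAsFactors = FALSE)
    }))
    key <- function(u, d) paste(u, d, sep = "|")
    se_key <- key(pairs$up, pairs$down)
    all_pairs$se_truth <- pairs$se_truth[match(key(all_pairs$up, all_pairs$down),
                                               se_key)]
    flank_genes <- unique(c(pairs$up, pairs$down))
    species <- names(config$species_divergence)
    syn_rows <- list(); ann_list <- list(); seq_list <- list()
    motif_rows <- list(); status_rows <- list(); bg_status_rows <- list()
    for (sp in species) {
      div <- config$species_divergence[[sp]]
      tgt_gene <- function(id) paste0(sp, "_", id)
      drop_genes <- character(0)
      insert_after <- character(0)   # query gene ids after which to insert
      all_status <- character(nrow(all_pairs))
      for (pi in seq_len(nrow(all_pairs))) {
        is_se <- !is.na(all_pairs$se_truth[pi])
        p_break <- if (is_se) config$synteny_break_prob
        else config$background_break_prob
        if (stats::runif(1) < p_break) {
          cand <- c(all_pairs$up[pi], all_pairs$down[pi])
          # never drop a gene that flanks a planted SE from a background
          # break: it would corrupt the SE-pair truth
          if (!is_se) cand <- setdiff(cand, flank_genes)
          if (stats::runif(1) < 0.5 && length(cand) > 0) {
            drop_genes <- c(drop_genes, sample(cand, 1))
            all_status[pi] <- "absent"
          } else {
            insert_after <- c(insert_after, all_pairs$up[pi])
            all_status[pi] <- "syntenic_nonadjacent"
          }
        } else all_status[pi] <- "syntenic_adjacent"
      }
      is_se_pair <- !is.na(all_pairs$se_truth)
      status <- all_status[match(se_key, key(all_pairs$up, all_pairs$down))]
      # target annotation mirrors query gene order with uniform spacing
      t_genes <- list()
      pos <- 0L; k <- 0L
      for (ci in unique(g$chrom)) {
        gg <- g[g$chrom == ci, ]
        gg <- gg[order(gg$start), ]
        pos <- 0L
        for (r in seq_len(nrow(gg))) {
          k <- k + 1L
          t_genes[[k]] <- data.frame(
            gene_id = tgt_gene(gg$gene_id[r]), chrom = paste0(sp, "_", ci),
            start = pos, end = pos + 1000L, strand = gg$strand[r],
            stringsAsFactors = FALSE)
          pos <- pos + 3000L
          if (gg$gene_id[r] %in% insert_after) {
            k <- k + 1L
            t_genes[[k]] <- data.frame(
              gene_id = paste0(sp, "_INS", k), chrom = paste0(sp, "_", ci),
              start = pos, end = pos + 1000L, strand = "+",
              stringsAsFactors = FALSE)
            pos <- pos + 3000L
          }
        }
      }
      t_ann <- gene_models(do.call(rbind, t_genes))
      ann_list[[sp]] <- t_ann
      syn_rows[[sp]] <- data.frame(
        species = sp,
        query_gene = setdiff(g$gene_id, drop_genes),
        target_gene = tgt_gene(setdiff(g$gene_id, drop_genes)),
        block_id = paste0(sp, "_B1"), stringsAsFactors = FALSE)
      # ortholog intergenic sequences for syntenic-adjacent pairs
      seqs <- character(0); mrows <- list()
      for (pi in which(status == "syntenic_adjacent")) {
        se_i <- se[se$se_truth == pairs$se_truth[pi], ]
        qseq <- genome_sequence(context$genome, se_i$chrom, se_i$start, se_i$end)
        mseq <- mutate_sequence(qseq, div, config$indel_rate)
        pad1 <- random_dna(sample(100:300, 1))
        pad2 <- random_dna(sample(100:300, 1))
        full <- paste0(pad1, mseq, pad2)
        seqs[[pairs$se_truth[pi]]] <- full
        present <- names(vocab)[vapply(vocab, function(w)
          grepl(w, full, fixed = TRUE), logical(1))]
        if (length(present)) {
          mrows[[length(mrows) + 1]] <- data.frame(
            species = sp, se_truth = pairs$se_truth[pi],
            motif_id = present, stringsAsFactors = FALSE)
        }
      }
      seq_list[[sp]] <- seqs
      motif_rows[[sp]] <- if (length(mrows)) do.call(rbind, mrows) else NULL
      status_rows[[sp]] <- data.frame(species = sp,
                                      se_truth = pairs$se_truth,
                                      status = status,
                                      divergence = div,
                                      stringsAsFactors = FALSE)
      bg_status_rows[[sp]] <- data.frame(species = sp,
                                         up = all_pairs$up[!is_se_pair],
                                         down = all_pairs$down[!is_se_pair],
                                         status = all_status[!is_se_pair],
                                         stringsAsFactors = FALSE)
    }
    list(synteny = do.call(rbind, syn_rows),
         target_annotations = ann_list,
         ortholog_seqs = seq_list,
         ortholog_motifs = do.call(rbind, motif_rows),
         truth = list(pairs = pairs,
                      status = do.call(rbind, status_rows),
                      background_status = do.call(rbind, bg_status_rows)))
  })
}

#' Simulate junction read-pair libraries for insertion loci
#'
#' Loci get alternating present/absent truth genotypes. Present loci yield
#' pairs spanning the left and right joints only; absent loci span the
#' cross joint only. Mates are exact substrings (mate2 reverse-
#' complemented) drawn on opposite sides of the joint midpoint.
#'
#' @param config a [simulation_config()].
#' @param genome a [genome_index()] with sequence.
#' @return List: `loci` (chrom, insertion_point, element, truth genotype),
#'   `junctions` (per locus), `read_pairs` (per locus data.frame
#'   mate1/mate2), `truth` (genotype table).
#' @export
simulate_insertion_libraries <- function(config, genome) {
  with_seed(config$seed + 505L, {
    chroms <- names(genome$seqlengths)
    flank <- config$junction_flank
    rl <- config$read_len
    loci <- lapply(seq_len(config$n_insertion_loci), function(i) {
      ch <- sample(chroms, 1L)
      pt <- sample(seq(flank + 10L, genome$seqlengths[[ch]] - flank - 10L), 1L)
      list(locus_id = sprintf("LOC%02d", i), chrom = ch, insertion_point = pt,
           element = random_dna(config$insertion_element_len),
           genotype = if (i %% 2L == 1L) "present" else "absent")
    })
    junctions <- lapply(loci, function(lc)
      build_junctions(genome, lc$element, lc$chrom, lc$insertion_point, flank))
    draw_pairs <- function(ref, n) {
      mid <- flank
      m1s <- sample(seq(0L, mid - rl), n, replace = TRUE)
      m2s <- sample(seq(mid, 2L * flank - rl), n, replace = TRUE)
      m1 <- substring(ref, m1s + 1L, m1s + rl)
      m2 <- vapply(substring(ref, m2s + 1L, m2s + rl), function(s)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
        character(1), USE.NAMES = FALSE)
      data.frame(mate1 = m1, mate2 = m2, stringsAsFactors = FALSE)
    }
    read_pairs <- lapply(seq_along(loci), function(i) {
      jc <- junctions[[i]]
      if (loci[[i]]$genotype == "present") {
        rbind(draw_pairs(jc$left_joint, config$pairs_per_junction),
              draw_pairs(jc$right_joint, config$pairs_per_junction))
      } else {
        draw_pairs(jc$cross_joint, config$pairs_per_junction)
      }
    })
    names(read_pairs) <- vapply(loci, `[[`, character(1), "locus_id")
    truth <- data.frame(
      locus_id = vapply(loci, `[[`, character(1), "locus_id"),
      genotype = vapply(loci, `[[`, character(1), "genotype"),
      stringsAsFactors = FALSE)
    list(loci = loci, junctions = junctions, read_pairs = read_pairs,
         truth = truth)
  })
}

#' Run the full synthetic study generator
#'
#' @param config a [simulation_config()].
#' @return List of class `se_simulation` bundling genome, annotation,
#'   landscape, context, ortholog panel, insertion libraries, and a merged
#'   `truth` list.
#' @export
simulate_se_study <- function(config = simulation_config()) {
  ann <- simulate_genome_and_annotation(config)
  landscape <- plant_accessibility_landscape(config, ann)
  context <- simulate_context(config, ann, landscape)
  ann$genome <- context$genome      # motif words planted into the sequence
  panel <- simulate_ortholog_panel(config, ann, landscape, context)
  ins <- simulate_insertion_libraries(config, ann$genome)
  out <- list(config = config, genome = ann$genome, genes = ann$genes,
              landscape = landscape, context = context, panel = panel,
              insertions = ins,
              truth = c(ann$truth, landscape$truth, context$truth,
                        panel$truth, list(insertions = ins$truth)))
  class(out) <- "se_simulation"
  out
}

#' @export
print.se_simulation <- function(x, ...) {
  cat("synthetic SE study:", length(x$genome$seqlengths), "chromosomes,",
      nrow(x$genes$genes), "genes,", nrow(x$truth$ses), "planted SEs,",
      length(x$landscape$sample_peaks), "samples\n")
  invisible(x)
}
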