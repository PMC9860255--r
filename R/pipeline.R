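#' Run the SE discovery and characterization pipeline on a simulated study
#'
#' Executes every analysis stage on the outputs of [simulate_se_study()]:
#' union-ACR atlas and promoter classification, nonpromoter clustering and
#' SE selection, cognate-gene assignment and position classes, atlas
#' summary, TAD membership with an empirical enrichment test against
#' size-matched random nongenic regions, loop filtering and SE-gene
#' linking, cognate-expression comparison, TF occupancy and enrichment
#' scan, cross-species conservation (spanning pairs, synteny status,
#' ortholog search, motif retention, maintenance statistic), insertion
#' genotyping, and evaluation against the planted truth.
#'
#' @param sim an `se_simulation` from [simulate_se_study()].
#' @param se_mode SE selection rule: `"quantile"` (top fraction) or
#'   `"length"` (bp threshold); see [select_super_enhancers()].
#' @param top_fraction,se_min_length selection parameters.
#' @param n_random_sets random nongenic sets for the TAD enrichment test.
#' @param n_maintenance_resamples resamples for the synteny-maintenance
#'   test.
#' @param min_identity local-alignment identity threshold for ortholog
#'   discovery.
#' @param cluster_gap largest gap (bp, inclusive) chaining nonpromoter ACRs.
#' @param seed seed for the pipeline's own randomness (region placement,
#'   resampling).
#' @return List of class `se_report` with one element per stage plus
#'   `evaluation` (truth comparison) and `provenance`.
#' @export
run_se_pipeline <- function(sim, se_mode = c("quantile", "length"),
                            top_fraction = 0.025, se_min_length = 1500L,
                            n_random_sets = 1000L,
                            n_maintenance_resamples = 1000L,
                            min_identity = 0.70, cluster_gap = 49L,
                            seed = 1L) {
  se_mode <- match.arg(se_mode)
  cfg <- sim$config
  gm <- sim$genes

  ## --- atlas ---------------------------------------------------------
  acrs <- build_union_acrs(sim$landscape$sample_peaks)
  acrs <- classify_acrs(acrs, gm, upstream_bp = cfg$promoter_upstream)

  ## --- SE calling ----------------------------------------------------
  clusters <- cluster_nonpromoter_acrs(acrs, max_gap = cluster_gap)
  sel <- select_super_enhancers(clusters, top_fraction = top_fraction,
                                mode = se_mode, min_length = se_min_length)
  quant <- select_super_enhancers(clusters, top_fraction = top_fraction,
                                  mode = "quantile")
  ses <- sel$ses
  ses <- assign_cognate_gene(ses, gm)
  ses <- classify_se_position(ses, gm)
  summary <- summarize_atlas(acrs, clusters, ses,
                             se_length_threshold = sel$se_length_threshold)

  ## --- TAD / loop context -------------------------------------------
  tads <- sim$context$tads
  tad_frac <- fraction_within_tads(ses, tads)
  rand_sets <- sample_random_nongenic(sim$genome, gm,
                                      size_list = ses$end - ses$start,
                                      n_sets = n_random_sets,
                                      seed = seed + 11L)
  null_frac <- vapply(rand_sets, fraction_within_tads, numeric(1), tads = tads)
  tad_enrichment <- empirical_enrichment_test(tad_frac, null_frac, "greater")
  se_gene_links <- filter_and_link_loops(sim$context$loops, ses, gm)

  ## --- expression ----------------------------------------------------
  np_other <- acrs[acrs$acr_class == "nonpromoter", , drop = FALSE]
  np_other <- np_other[!overlaps_any(np_other, ses), , drop = FALSE]
  np_other <- assign_cognate_gene(np_other, gm)
  se_genes <- unique(stats::na.omit(ses$cognate_gene))
  other_genes <- setdiff(unique(stats::na.omit(np_other$cognate_gene)), se_genes)
  expr_cmp <- compare_cognate_expression(sim$context$expression,
                                         se_genes, other_genes)

  ## --- TF occupancy --------------------------------------------------
  constituent <- acrs$acr_class == "nonpromoter" & overlaps_any(acrs, ses)
  acr_group <- ifelse(acrs$acr_class == "promoter", "promoter",
                      ifelse(constituent, "constituent", "other_nonpromoter"))
  occupancy <- tf_occupancy(acrs, sim$context$tf_peaks)
  tf_counts <- tf_counts_per_acr(occupancy)
  tf_scan <- enrichment_scan(occupancy, acr_group, "constituent", "promoter")
  se_motifs <- motif_catalog(ses, sim$context$motif_hits)

  ## --- conservation --------------------------------------------------
  pairs <- se_spanning_pairs(ses, gm)
  status <- syntenic_status(pairs, sim$panel$synteny,
                            sim$panel$target_annotations)
  # map called SEs onto planted SEs to fetch panel ortholog sequences
  truth_se <- sim$truth$ses
  se_map <- rep(NA_character_, nrow(ses))
  for (i in seq_len(nrow(ses))) {
    hit <- which(truth_se$chrom == ses$chrom[i] &
                   truth_se$start < ses$end[i] & truth_se$end > ses$start[i])
    if (length(hit) == 1) se_map[i] <- truth_se$se_truth[hit]
  }
  ortho_rows <- list(); ret_rows <- list()
  for (i in seq_len(nrow(ses))) {
    tid <- se_map[i]
    if (is.na(tid)) next
    qseq <- genome_sequence(sim$genome, ses$chrom[i], ses$start[i], ses$end[i])
    qmot <- sim$context$motif_hits$motif_id[
      sim$context$motif_hits$se_truth == tid]
    for (sp in names(sim$panel$ortholog_seqs)) {
      st <- status$status[status$se_id == ses$se_id[i] &
                            status$species == sp]
      if (!length(st) || st != "syntenic_adjacent") next
      tseq <- sim$panel$ortholog_seqs[[sp]][[tid]]
      if (is.null(tseq)) next
      hit <- ortholog_se_search(qseq, tseq, min_identity = min_identity)
      if (!is.null(hit)) {
        ortho_rows[[length(ortho_rows) + 1]] <- data.frame(
          se_id = ses$se_id[i], species = sp,
          aligned_fraction = hit$aligned_fraction, identity = hit$identity,
          stringsAsFactors = FALSE)
      }
      omot <- sim$panel$ortholog_motifs$motif_id[
        sim$panel$ortholog_motifs$species == sp &
          sim$panel$ortholog_motifs$se_truth == tid]
      ret <- motif_retention(qmot, omot)
      ret_rows[[length(ret_rows) + 1]] <- data.frame(
        se_id = ses$se_id[i], species = sp,
        n_motifs_query = ret$n_motifs_query, n_retained = ret$n_retained,
        retention_rate = ret$retention_rate, stringsAsFactors = FALSE)
    }
  }
  ortho_hits <- if (length(ortho_rows)) do.call(rbind, ortho_rows)
  else data.frame(se_id = character(), species = character(),
                  aligned_fraction = numeric(), identity = numeric())
  retention <- if (length(ret_rows)) do.call(rbind, ret_rows)
  else data.frame(se_id = character(), species = character(),
                  n_motifs_query = integer(), n_retained = integer(),
                  retention_rate = numeric())
  cons_report <- conservation_report(status, ortho_hits, ses = ses, cns = NULL)

  # synteny maintenance: SE-spanning pairs vs all other consecutive pairs
  n_species <- length(sim$panel$target_annotations)
  with_counts <- tapply(status$status == "syntenic_adjacent",
                        status$se_id, sum)
  bg <- sim$panel$truth$background_status
  bg_pairs <- unique(bg[, c("up", "down")])
  bg_pairs$se_id <- paste0("BGP", seq_len(nrow(bg_pairs)))
  bg_pairs$upstream_gene <- bg_pairs$up
  bg_pairs$downstream_gene <- bg_pairs$down
  bg_pairs$skipped <- FALSE
  bg_status <- syntenic_status(bg_pairs, sim$panel$synteny,
                               sim$panel$target_annotations)
  without_counts <- tapply(bg_status$status == "syntenic_adjacent",
                           bg_status$se_id, sum)
  maintenance <- synteny_maintenance(
    as.integer(with_counts), as.integer(without_counts),
    min_species = cfg$maintenance_min_species,
    n_resamples = n_maintenance_resamples, seed = seed + 23L)

  ## --- insertion genotyping ------------------------------------------
  geno_rows <- lapply(seq_along(sim$insertions$loci), function(i) {
    lc <- sim$insertions$loci[[i]]
    jc <- build_junctions(sim$genome, lc$element, lc$chrom,
                          lc$insertion_point, cfg$junction_flank)
    ev <- count_spanning_pairs(sim$insertions$read_pairs[[lc$locus_id]], jc)
    call <- classify_insertion(ev)
    data.frame(locus_id = lc$locus_id, call = call$call,
               n_left = ev$n_left, n_right = ev$n_right,
               n_cross = ev$n_cross, stringsAsFactors = FALSE)
  })
  genotypes <- do.call(rbind, geno_rows)

  ## --- evaluation against truth --------------------------------------
  evaluation <- evaluate_against_truth(sim, ses, acrs, genotypes, se_map)

  out <- list(
    acrs = acrs, clusters = clusters, ses = ses,
    se_length_threshold = sel$se_length_threshold,
    quantile_threshold = quant$se_length_threshold,
    summary = summary,
    tad_fraction = tad_frac, tad_enrichment = tad_enrichment,
    se_gene_links = se_gene_links, expression = expr_cmp,
    occupancy = occupancy, tf_counts = tf_counts, tf_scan = tf_scan,
    se_motifs = se_motifs,
    spanning_pairs = pairs, synteny_status = status,
    ortholog_hits = ortho_hits, motif_retention = retention,
    conservation = cons_report, maintenance = maintenance,
    genotypes = genotypes, evaluation = evaluation,
    provenance = list(package = "sepal",
                      version = as.character(utils::packageVersion("sepal")),
                      seed = seed, se_mode = se_mode,
                      sim_seed = cfg$seed))
  class(out) <- "se_report"
  out
}

# truth-table comparison: planted-SE recovery, ACR class agreement,
# genotype accuracy
evaluate_against_truth <- function(sim, ses, acrs, genotypes, se_map) {
  truth_se <- sim$truth$ses
  matched <- function(a, b) {
    # reciprocal >= 50% overlap
    ov <- max(0L, min(a$end, b$end) - max(a$start, b$start))
    a$chrom == b$chrom && ov >= 0.5 * (a$end - a$start) &&
      ov >= 0.5 * (b$end - b$start)
  }
  recovered <- vapply(seq_len(nrow(truth_se)), function(t) {
    any(vapply(seq_len(nrow(ses)), function(i)
      matched(truth_se[t, ], ses[i, ]), logical(1)))
  }, logical(1))
  correct_call <- vapply(seq_len(nrow(ses)), function(i) {
    any(vapply(seq_len(nrow(truth_se)), function(t)
      matched(truth_se[t, ], ses[i, ]), logical(1)))
  }, logical(1))
  # ACR class agreement against planted site classes
  sites <- sim$truth$sites
  acr_truth_class <- rep(NA_character_, nrow(acrs))
  for (i in seq_len(nrow(acrs))) {
    hit <- which(sites$chrom == acrs$chrom[i] &
                   sites$start < acrs$end[i] & sites$end > acrs$start[i])
    if (length(hit)) {
      acr_truth_class[i] <- if (any(sites$class[hit] == "promoter"))
        "promoter" else "nonpromoter"
    }
  }
  known <- !is.na(acr_truth_class)
  class_agreement <- mean(acrs$acr_class[known] == acr_truth_class[known])
  geno <- merge(genotypes, sim$truth$insertions, by = "locus_id")
  list(se_recall = mean(recovered),
       se_precision = if (nrow(ses)) mean(correct_call) else NA_real_,
       n_planted = nrow(truth_se), n_called = nrow(ses),
       acr_class_agreement = class_agreement,
       genotype_accuracy = mean(geno$call == geno$genotype))
}

#' @export
print.se_report <- function(x, ...) {
  cat("SE pipeline report\n")
  print(x$summary)
  cat(sprintf("  SE TAD membership: %.3f (empirical p = %.4g)\n",
              x$tad_fraction, x$tad_enrichment$p_value))
  cat(sprintf("  synteny maintenance: %.1f%% with SE vs %.1f%% without (p = %.4g)\n",
              x$maintenance$percent_with, x$maintenance$percent_without,
              x$maintenance$p_value))
  cat(sprintf("  planted-SE recall %.2f, precision %.2f; genotype accuracy %.2f\n",
              x$evaluation$se_recall, x$evaluation$se_precision,
              x$evaluation$genotype_accuracy))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits deterministic TSV tables plus a `report.json` with the headline
#' numbers and provenance (package version, seeds, configuration of the
#' run). Two runs with identical seeds produce byte-identical bundles.
#'
#' @param report an `se_report` from [run_se_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$acrs, file.path(dir, "acrs.tsv"))
  write_tsv(report$clusters, file.path(dir, "clusters.tsv"))
  write_tsv(report$ses, file.path(dir, "ses.tsv"))
  write_tsv(report$tf_scan, file.path(dir, "tf_enrichment.tsv"))
  write_tsv(report$se_gene_links, file.path(dir, "se_gene_links.tsv"))
  write_tsv(report$synteny_status, file.path(dir, "synteny_status.tsv"))
  write_tsv(report$ortholog_hits, file.path(dir, "ortholog_hits.tsv"))
  write_tsv(report$motif_retention, file.path(dir, "motif_retention.tsv"))
  write_tsv(report$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv(report$expression, file.path(dir, "expression_tests.tsv"))
  smry <- report$summary
  json <- list(
    summary = unclass(smry),
    se_length_threshold = report$se_length_threshold,
    quantile_threshold = report$quantile_threshold,
    tad_fraction = report$tad_fraction,
    tad_enrichment_p = report$tad_enrichment$p_value,
    maintenance = report$maintenance[c("percent_with", "percent_without",
                                       "p_value")],
    conservation_per_species = report$conservation$per_species,
    evaluation = report$evaluation,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a simulated study to a directory of standard-format files
#'
#' Emits `genome.fa`, `genes.gff3`, per-sample peak BEDs and read-start
#' TSVs, `tads.bed`, `loops.tsv`, per-TF peak BEDs, `motifs.tsv`,
#' `expression.tsv`, `synteny.tsv`, per-species ortholog FASTA and target
#' annotation TSVs, insertion read-pair TSVs, and truth tables as JSON.
#'
#' @param sim an `se_simulation`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tf"), showWarnings = FALSE)
  dir.create(file.path(dir, "ortholog"), showWarnings = FALSE)
  dir.create(file.path(dir, "insertions"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome$sequences, file.path(dir, "genome.fa"))
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  for (sid in names(sim$landscape$sample_peaks)) {
    write_bed(sim$landscape$sample_peaks[[sid]],
              file.path(dir, "samples", paste0(sid, ".bed")))
    tr <- sim$landscape$tracks[[sid]]
    reads <- do.call(rbind, lapply(tr, function(t)
      data.frame(chrom = t$chrom, position = t$positions)))
    write_tsv(reads, file.path(dir, "samples", paste0(sid, ".reads.tsv")))
  }
  write_bed(sim$context$tads, file.path(dir, "tads.bed"))
  write_tsv(sim$context$loops, file.path(dir, "loops.tsv"))
  for (tf in names(sim$context$tf_peaks)) {
    write_bed(sim$context$tf_peaks[[tf]], file.path(dir, "tf", paste0(tf, ".bed")))
  }
  write_tsv(sim$context$motif_hits, file.path(dir, "motifs.tsv"))
  expr <- data.frame(gene_id = rownames(sim$context$expression),
                     sim$context$expression, check.names = FALSE)
  write_tsv(expr, file.path(dir, "expression.tsv"))
  write_tsv(sim$panel$synteny, file.path(dir, "synteny.tsv"))
  for (sp in names(sim$panel$ortholog_seqs)) {
    seqs <- sim$panel$ortholog_seqs[[sp]]
    if (length(seqs)) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)),
                                  file.path(dir, "ortholog", paste0(sp, ".fa")))
    }
    write_tsv(sim$panel$target_annotations[[sp]]$genes,
              file.path(dir, "ortholog", paste0(sp, "_genes.tsv")))
  }
  for (lc in sim$insertions$loci) {
    write_tsv(sim$insertions$read_pairs[[lc$locus_id]],
              file.path(dir, "insertions", paste0(lc$locus_id, ".reads.tsv")))
  }
  loci <- do.call(rbind, lapply(sim$insertions$loci, function(lc)
    data.frame(locus_id = lc$locus_id, chrom = lc$chrom,
               insertion_point = lc$insertion_point, element = lc$element,
               stringsAsFactors = FALSE)))
  write_tsv(loci, file.path(dir, "insertions", "loci.tsv"))
  truth <- sim$truth
  truth$motif_vocab <- as.list(truth$motif_vocab)
  jsonlite::write_json(truth, file.path(dir, "truth", "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' @param gm a [gene_models()] object.
#' @param path output file.
#' @export
write_gff3 <- function(gm, path) {
  g <- gm$genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    lines <- c(lines,
               paste(g$chrom[i], "sepal_sim", "gene", g$start[i] + 1L, g$end[i],
                     ".", g$strand[i], ".", paste0("ID=", id), sep = "\t"),
               paste(g$chrom[i], "sepal_sim", "mRNA", g$start[i] + 1L, g$end[i],
                     ".", g$strand[i], ".",
                     paste0("ID=", id, ".1;Parent=", id), sep = "\t"))
    ex <- gm$exons[gm$exons$gene_id == id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
                 paste(ex$chrom[j], "sepal_sim", "exon", ex$start[j] + 1L,
                       ex$end[j], ".", g$strand[i], ".",
                       paste0("ID=", id, ".1.e", j, ";Parent=", id, ".1"),
                       sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
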