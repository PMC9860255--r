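test_that("genome and annotation simulation is deterministic and well formed", {
  cfg <- simulation_config(seed = 11, n_genes = 40L, chrom_length = 300000L)
  a <- simulate_genome_and_annotation(cfg)
  b <- simulate_genome_and_annotation(cfg)
  expect_identical(as.character(a$genome$sequences),
                   as.character(b$genome$sequences))
  expect_identical(a$genes$genes, b$genes$genes)
  expect_identical(a$genes$exons, b$genes$exons)

  g <- a$genes$genes
  # genes are non-overlapping and sorted within chromosome
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  # exons partition within the gene body
  for (id in sample(g$gene_id, 10)) {
    ex <- a$genes$exons[a$genes$exons$gene_id == id, ]
    gi <- g[g$gene_id == id, ]
    expect_true(all(ex$start >= gi$start & ex$end <= gi$end))
    expect_true(all(diff(ex$start) > 0))
  }

  # gene-free genome is allowed
  empty <- simulate_genome_and_annotation(
    simulation_config(seed = 1, n_genes = 0L, chrom_length = 50000L))
  expect_equal(nrow(empty$genes$genes), 0L)
})

test_that("planted landscape respects the SE construction rules", {
  cfg <- simulation_config(seed = 12)
  ann <- simulate_genome_and_annotation(cfg)
  ls <- plant_accessibility_landscape(cfg, ann)
  se <- ls$truth$ses
  con <- ls$truth$constituents
  expect_equal(nrow(se), cfg$n_planted_ses)
  # every planted SE is at least the minimum length
  expect_true(all(se$end - se$start >= cfg$min_planted_se_length))
  # constituent gaps inside each SE are < 50 bp
  for (id in se$se_truth) {
    cc <- con[con$se_truth == id, ]
    cc <- cc[order(cc$start), ]
    if (nrow(cc) > 1) {
      gaps <- cc$start[-1] - cc$end[-nrow(cc)]
      expect_true(all(gaps >= 20 & gaps <= 45))
    }
  }
  # background ACRs are >= 200 bp from any planted SE
  bg <- ls$truth$background
  for (i in seq_len(nrow(bg))) {
    same <- se[se$chrom == bg$chrom[i], ]
    if (nrow(same)) {
      d <- pmax(same$start - bg$end[i], bg$start[i] - same$end)
      expect_true(all(d >= 200))
    }
  }
  # each sample has at least one peak; peaks are valid intervals
  for (pk in ls$sample_peaks) {
    expect_gt(nrow(pk), 0)
    expect_true(all(pk$end > pk$start))
  }
})

test_that("TAD planting hits the exact designed membership count", {
  cfg <- simulation_config(seed = 13)
  ann <- simulate_genome_and_annotation(cfg)
  ls <- plant_accessibility_landscape(cfg, ann)
  ctx <- simulate_context(cfg, ann, ls)
  n_in <- sum(ctx$truth$tad_membership$in_tad)
  expect_equal(n_in, round(cfg$tad_enrichment * cfg$tad_coverage *
                             cfg$n_planted_ses))
  # the membership truth matches containment against the emitted TADs
  se <- ls$truth$ses
  got <- vapply(seq_len(nrow(se)), function(i) {
    t <- ctx$tads[ctx$tads$chrom == se$chrom[i], ]
    any(t$start <= se$start[i] & t$end >= se$end[i])
  }, logical(1))
  expect_equal(got, ctx$truth$tad_membership$in_tad)
  # TAD coverage is near the configured fraction
  cov <- sum(ctx$tads$end - ctx$tads$start) /
    (cfg$n_chromosomes * cfg$chrom_length)
  expect_lt(abs(cov - cfg$tad_coverage), 0.05)
})

test_that("planted loops pass the FDR filter and decoys do not", {
  cfg <- simulation_config(seed = 14)
  ann <- simulate_genome_and_annotation(cfg)
  ls <- plant_accessibility_landscape(cfg, ann)
  ctx <- simulate_context(cfg, ann, ls)
  keep <- ctx$loops$fdr < 1e-10
  expect_equal(sum(keep), cfg$n_planted_ses)
  expect_equal(sum(!keep), cfg$n_decoy_loops)
})

test_that("planted motif words are recoverable from the genome sequence", {
  cfg <- simulation_config(seed = 15)
  ann <- simulate_genome_and_annotation(cfg)
  ls <- plant_accessibility_landscape(cfg, ann)
  ctx <- simulate_context(cfg, ann, ls)
  mh <- ctx$motif_hits
  vocab <- ctx$truth$motif_vocab
  genome <- ctx$genome
  for (i in sample(nrow(mh), 20)) {
    got <- genome_sequence(genome, mh$chrom[i], mh$start[i], mh$end[i])
    expect_equal(got, unname(vocab[[mh$motif_id[i]]]))
  }
})

test_that("ortholog panel divergence, breaks, and motif hits match design", {
  cfg <- simulation_config(seed = 16)
  sim <- simulate_se_study(cfg)
  st <- sim$panel$truth$status
  # all species represented, statuses legal
  expect_setequal(unique(st$species), names(cfg$species_divergence))
  expect_true(all(st$status %in% c("syntenic_adjacent", "syntenic_nonadjacent",
                                   "absent")))
  # ortholog sequences exist exactly for syntenic-adjacent SE pairs
  for (sp in names(cfg$species_divergence)) {
    adj <- st$se_truth[st$species == sp & st$status == "syntenic_adjacent"]
    expect_setequal(names(sim$panel$ortholog_seqs[[sp]]), adj)
  }
  # break probability is roughly respected across species x pairs
  broken <- mean(st$status != "syntenic_adjacent")
  expect_lt(abs(broken - cfg$synteny_break_prob), 0.12)
})

test_that("the full simulation is reproducible end to end", {
  cfg <- simulation_config(seed = 17, n_genes = 60L, chrom_length = 300000L,
                           n_planted_ses = 6L, n_background_acrs = 60L,
                           n_insertion_loci = 2L)
  a <- simulate_se_study(cfg)
  b <- simulate_se_study(cfg)
  expect_identical(as.character(a$genome$sequences),
                   as.character(b$genome$sequences))
  expect_identical(a$truth$ses, b$truth$ses)
  expect_identical(a$context$tads, b$context$tads)
  expect_identical(a$panel$synteny, b$panel$synteny)
  expect_identical(a$insertions$truth, b$insertions$truth)
  expect_identical(a$context$expression, b$context$expression)
})
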