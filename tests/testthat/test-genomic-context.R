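test_that("gene density applies the subtracted-length correction", {
  # 3 genes in the single full window, 3000 bp subtracted -> 15000*3/12000
  gm <- gene_models(data.frame(
    gene_id = c("G1", "G2", "G3"), chrom = "c1",
    start = c(1000L, 5000L, 9000L), end = c(2000L, 6000L, 10000L),
    strand = "+", stringsAsFactors = FALSE))
  genome <- genome_index(c(c1 = 15000L))
  sub <- gintervals("c1", 12000L, 15000L)
  wd <- gene_density_windows(gm, genome, sub)
  expect_equal(nrow(wd), 1L)
  expect_equal(wd$subtracted_length, 3000L)
  expect_equal(wd$density, 3.75)

  # no subtraction reduces to the naive count
  wd0 <- gene_density_windows(gm, genome, NULL)
  expect_equal(wd0$density, 3)
  expect_equal(wd0$subtracted_length, 0L)

  # zero genes stays zero regardless of subtraction
  empty <- gene_models(data.frame(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character()))
  expect_equal(gene_density_windows(empty, genome, sub)$density, 0)

  # fully covered window is flagged undefined
  all_sub <- gintervals("c1", 0L, 15000L)
  wfull <- gene_density_windows(gm, genome, all_sub)
  expect_true(wfull$undefined)
  expect_true(is.na(wfull$density))
})

test_that("fraction_within_tads distinguishes containment from overlap", {
  regions <- gintervals(rep("c1", 2), c(100L, 5000L), c(200L, 6000L))
  whole <- gintervals("c1", 0L, 10000L)
  expect_equal(fraction_within_tads(regions, whole), 1.0)
  expect_equal(fraction_within_tads(regions, whole[0, ]), 0.0)
  # region straddling the TAD edge: not contained, but >50% overlapping
  tad <- gintervals("c1", 0L, 5500L)
  straddle <- gintervals("c1", 5200L, 5600L)
  expect_equal(fraction_within_tads(straddle, tad), 0.0)
  expect_equal(fraction_within_tads(straddle, tad, rule = "overlap"), 1.0)
  expect_error(fraction_within_tads(regions[0, ], whole), "empty")
})

test_that("random nongenic placement respects constraints and seed", {
  cfg <- simulation_config(seed = 5, n_genes = 40L, chrom_length = 200000L)
  ann <- simulate_genome_and_annotation(cfg)
  sizes <- c(500L, 1500L, 2500L)
  sets <- sample_random_nongenic(ann$genome, ann$genes, sizes,
                                 n_sets = 20, seed = 9)
  expect_length(sets, 20)
  gb <- ann$genes$genes
  for (s in sets) {
    expect_equal(s$end - s$start, sizes)
    for (i in seq_len(nrow(s))) {
      g <- gb[gb$chrom == s$chrom[i], ]
      expect_false(any(s$start[i] < g$end & s$end[i] > g$start))
    }
  }
  sets2 <- sample_random_nongenic(ann$genome, ann$genes, sizes,
                                  n_sets = 20, seed = 9)
  expect_identical(sets, sets2)
  # a size that cannot fit errors with the size named
  expect_error(sample_random_nongenic(ann$genome, ann$genes, 150000L,
                                      n_sets = 1, seed = 1, max_tries = 50),
               "150000")
})

test_that("add-one empirical p-values behave at the extremes", {
  nulls <- seq_len(999) / 1000
  expect_equal(empirical_enrichment_test(2, nulls)$p_value, 1 / 1000)
  expect_equal(empirical_enrichment_test(-1, nulls)$p_value, 1.0)
  expect_gt(empirical_enrichment_test(0.5, nulls)$p_value, 0)
  # monotone non-increasing in the observed value
  p <- vapply(c(0.1, 0.5, 0.9, 1.1),
              function(o) empirical_enrichment_test(o, nulls)$p_value,
              numeric(1))
  expect_true(all(diff(p) <= 0))
  # mirrored alternative
  expect_equal(empirical_enrichment_test(-1, nulls, "less")$p_value, 1 / 1000)
  expect_error(empirical_enrichment_test(1, numeric(0)), "at least one")
})

test_that("loop filtering links SE and gene anchors below the FDR cutoff", {
  gm <- toy_genes()
  ses <- data.frame(se_id = "SE1", chrom = "c1", start = 4000L, end = 4800L)
  loops <- data.frame(chrom = "c1",
                      a1_start = c(4100L, 4100L), a1_end = c(4300L, 4300L),
                      a2_start = c(700L, 700L), a2_end = c(900L, 900L),
                      stat = c(50, 60), fdr = c(1e-12, 1))
  # one loop passes FDR; its gene anchor sits in GA's promoter window
  got <- filter_and_link_loops(loops, ses, gm)
  expect_equal(nrow(got), 1L)
  expect_equal(got$se_id, "SE1")
  expect_equal(got$gene_id, "GA")
  expect_equal(got$statistic, 50)

  none <- filter_and_link_loops(transform(loops, fdr = 1), ses, gm)
  expect_equal(nrow(none), 0L)

  bad <- transform(loops, fdr = c(2, 0.5))
  expect_error(filter_and_link_loops(bad, ses, gm), "malformed")
  expect_error(filter_and_link_loops(loops[, -1], ses, gm), "lacks column")
})

test_that("rank-sum comparison matches exhaustive enumeration and approximation", {
  expr <- cbind(t1 = c(3, 4, 5, 1, 2, 3))
  rownames(expr) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  got <- compare_cognate_expression(expr, c("a1", "a2", "a3"),
                                    c("b1", "b2", "b3"))
  expect_equal(got$p_value, 2 / 20)   # enumeration over C(6,3) assignments

  # identical sets: p >= 0.5
  expr2 <- cbind(t1 = c(1, 2, 3, 1, 2, 3))
  rownames(expr2) <- rownames(expr)
  p2 <- compare_cognate_expression(expr2, c("a1", "a2", "a3"),
                                   c("b1", "b2", "b3"))$p_value
  expect_gte(p2, 0.5)

  # all tied values are flagged with p = 1
  expr3 <- cbind(t1 = rep(1, 6))
  rownames(expr3) <- rownames(expr)
  got3 <- compare_cognate_expression(expr3, c("a1", "a2"), c("b1", "b2"))
  expect_equal(got3$p_value, 1)
  expect_true(got3$all_tied)

  # large-sample branch agrees with stats::wilcox.test
  set.seed(2)
  va <- rnorm(20, 1); vb <- rnorm(25)
  expr4 <- cbind(t1 = c(va, vb))
  rownames(expr4) <- c(paste0("a", 1:20), paste0("b", 1:25))
  got4 <- compare_cognate_expression(expr4, paste0("a", 1:20), paste0("b", 1:25))
  want <- wilcox.test(va, vb, alternative = "greater", exact = FALSE,
                      correct = TRUE)$p.value
  expect_equal(got4$p_value, want)

  expect_error(compare_cognate_expression(expr, "zz", "b1"), "non-empty")
})

test_that("a planted expression shift is detected in every tissue", {
  set.seed(7)
  n_a <- 20; n_b <- 200
  expr <- sapply(1:4, function(t) c(rnorm(n_a, 2), rnorm(n_b, 0)))
  rownames(expr) <- c(paste0("a", 1:n_a), paste0("b", 1:n_b))
  colnames(expr) <- paste0("t", 1:4)
  got <- compare_cognate_expression(expr, paste0("a", 1:n_a), paste0("b", 1:n_b))
  expect_true(all(got$p_value < 0.01))
})
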