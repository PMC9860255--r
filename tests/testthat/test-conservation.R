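test_that("spanning pairs take the nearest flanking genes and skip genic SEs", {
  gm <- toy_genes()  # GA [1000,3000), GB [6000,8000) on c1
  ses <- data.frame(se_id = c("S1", "S2", "S3"), chrom = "c1",
                    start = c(4000L, 100L, 1500L), end = c(4500L, 500L, 1700L),
                    position_class = c("intergenic", "intergenic",
                                       "genic_multifeature"),
                    stringsAsFactors = FALSE)
  got <- se_spanning_pairs(ses, gm)
  expect_equal(got$upstream_gene[1], "GA")
  expect_equal(got$downstream_gene[1], "GB")
  expect_false(got$skipped[1])
  expect_true(got$skipped[2])                 # no gene to the left
  expect_equal(got$reason[2], "chromosome_end")
  expect_true(got$skipped[3])
  expect_equal(got$reason[3], "genic")
})

synteny_fixture <- function() {
  # target annotation: partners adjacent for pair (GA,GB) in species spA;
  # one inserted gene between them in spB; GB unmapped in spC
  t_ann <- function(ids, starts) {
    gene_models(data.frame(gene_id = ids, chrom = "t1",
                           start = starts, end = starts + 500L,
                           strand = "+", stringsAsFactors = FALSE))
  }
  list(
    pairs = data.frame(se_id = "S1", upstream_gene = "GA",
                       downstream_gene = "GB", skipped = FALSE,
                       reason = NA_character_, stringsAsFactors = FALSE),
    synteny = data.frame(
      species = c("spA", "spA", "spB", "spB", "spC"),
      query_gene = c("GA", "GB", "GA", "GB", "GA"),
      target_gene = c("tA", "tB", "tA", "tB", "tA"),
      block_id = "B1", stringsAsFactors = FALSE),
    anns = list(
      spA = t_ann(c("tA", "tB"), c(0L, 1000L)),
      spB = t_ann(c("tA", "tX", "tB"), c(0L, 1000L, 2000L)),
      spC = t_ann(c("tA", "tB"), c(0L, 1000L))))
}

test_that("syntenic status distinguishes adjacency, insertion, and absence", {
  fx <- synteny_fixture()
  got <- syntenic_status(fx$pairs, fx$synteny, fx$anns)
  expect_equal(got$status[got$species == "spA"], "syntenic_adjacent")
  expect_equal(got$status[got$species == "spB"], "syntenic_nonadjacent")
  expect_equal(got$status[got$species == "spC"], "absent")

  bad_syn <- fx$synteny
  bad_syn$target_gene[1] <- "missing_gene"
  expect_error(syntenic_status(fx$pairs, bad_syn, fx$anns), "missing_gene")
})

test_that("local alignment of identical sequences is a single perfect hit", {
  set.seed(21)
  s <- random_dna_str(500)
  hits <- local_align(s, s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1)
  expect_equal(hits$q_start, 0L)
  expect_equal(hits$q_end, 500L)
  expect_equal(hits$score, 500)   # match * length against itself
  res <- ortholog_se_search(s, s)
  expect_equal(res$aligned_fraction, 100)
  expect_equal(res$identity, 100)
})

test_that("unrelated random sequences yield no accepted hit", {
  for (seed in 1:20) {
    set.seed(seed + 300)
    q <- random_dna_str(400)
    t <- random_dna_str(400)
    expect_null(ortholog_se_search(q, t))
  }
})

test_that("planted substitutions are recovered as identity within 2 points", {
  set.seed(22)
  ids <- replicate(10, {
    q <- random_dna_str(2000)
    t <- mutate_k(q, 200)   # exactly 10% divergence
    hits <- local_align(q, t, min_identity = 0.5)
    100 * sum(hits$matches) / sum(hits$columns)
  })
  expect_lt(abs(mean(ids) - 90), 2)
})

test_that("alignment summaries are reverse-complement invariant", {
  set.seed(23)
  q <- random_dna_str(600)
  t <- mutate_k(q, 30)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  a <- ortholog_se_search(q, t)
  b <- ortholog_se_search(rc(q), rc(t))
  expect_equal(a$identity, b$identity, tolerance = 1e-9)
  expect_equal(a$aligned_fraction, b$aligned_fraction, tolerance = 1e-9)
  # reverse-complementing only the target flips the hit strand
  c <- ortholog_se_search(q, rc(t))
  expect_equal(c$identity, a$identity, tolerance = 1e-9)
  expect_setequal(unique(c$hits$strand), "-")
})

test_that("iterated masking extracts multiple disjoint hits", {
  set.seed(24)
  block1 <- random_dna_str(200)
  block2 <- random_dna_str(200)
  # the unrelated middle is long enough that bridging the two blocks in a
  # single local alignment cannot pay for its gap/mismatch cost
  q <- paste0(block1, random_dna_str(600), block2)
  t <- paste0(random_dna_str(100), block1, random_dna_str(100), block2)
  hits <- local_align(q, t, min_hit_len = 100)
  expect_equal(nrow(hits), 2L)
  # query intervals are pairwise disjoint
  hits <- hits[order(hits$q_start), ]
  expect_true(all(hits$q_start[-1] >= hits$q_end[-nrow(hits)]))
  res <- ortholog_se_search(q, t, min_hit_len = 100)
  expect_lt(abs(res$aligned_fraction - 100 * 400 / 1000), 6)
})

test_that("local alignment score equals the exhaustive DP oracle on short pairs", {
  for (seed in 1:25) {
    set.seed(seed + 500)
    q <- random_dna_str(sample(20:50, 1))
    t <- if (seed %% 2) mutate_k(q, 3) else random_dna_str(sample(20:50, 1))
    got <- local_align(q, t, min_identity = 0, min_hit_len = 1, min_score = 1)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(t)))
    # the first extracted hit is the global optimum over both strands
    want <- max(oracle_sw_score(q, t), oracle_sw_score(q, rc))
    expect_equal(max(got$score), want)
  }
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("motif retention is presence-based with an undefined flag", {
  expect_equal(motif_retention(c("M1", "M2", "M3", "M4"),
                               c("M1", "M2", "M3", "M4"))$retention_rate, 100)
  got <- motif_retention(c("M1", "M2", "M3", "M4"), c("M1", "M2", "M4"))
  expect_equal(got$retention_rate, 75)
  expect_equal(got$n_retained, 3L)
  none <- motif_retention(character(0), c("M1"))
  expect_true(none$undefined)
  expect_true(is.na(none$retention_rate))
})

test_that("conservation report reproduces exact percentage arithmetic", {
  # 384 syntenic pairs in one species, 312 with ortholog hits -> 81%
  status <- data.frame(
    se_id = sprintf("S%03d", 1:498), species = "bra",
    status = c(rep("syntenic_adjacent", 384), rep("absent", 114)),
    stringsAsFactors = FALSE)
  hits <- data.frame(se_id = sprintf("S%03d", 1:312), species = "bra",
                     aligned_fraction = 80, identity = 70,
                     stringsAsFactors = FALSE)
  rep <- conservation_report(status, hits)
  expect_equal(rep$per_species$n_syntenic, 384L)
  expect_equal(rep$per_species$n_hit, 312L)
  expect_equal(rep$per_species$percent_hit, 81)
  expect_equal(rep$n_se_any_pair, 384L)

  # CNS containment: 363 of 498 -> 73%
  status2 <- data.frame(se_id = sprintf("S%03d", 1:498), species = "aly",
                        status = "syntenic_adjacent", stringsAsFactors = FALSE)
  ses <- data.frame(se_id = sprintf("S%03d", 1:498), chrom = "c1",
                    start = seq(0L, by = 1000L, length.out = 498))
  ses$end <- ses$start + 500L
  cns <- ses[1:363, c("chrom", "start", "end")]
  rep2 <- conservation_report(status2, hits, ses = ses, cns = cns)
  expect_equal(rep2$n_se_with_cns, 363L)
  expect_equal(rep2$percent_cns, 73)
})

test_that("synteny maintenance statistics and empirical p behave", {
  # extreme case: all with-SE pairs maintain, none in the pool
  res <- synteny_maintenance(rep(6L, 10), rep(0L, 100), min_species = 5,
                             n_resamples = 200, seed = 1)
  expect_equal(res$percent_with, 100)
  expect_equal(res$percent_without, 0)
  expect_equal(res$p_value, 1 / 201)

  # planted 20-point gap is detected
  set.seed(31)
  with_se <- rbinom(40, 6, 0.9)
  without <- rbinom(400, 6, 0.55)
  res2 <- synteny_maintenance(with_se, without, min_species = 5,
                              n_resamples = 1000, seed = 2)
  expect_lt(res2$p_value, 0.01)

  # identical pools: p is not extreme
  pool <- rbinom(500, 6, 0.7)
  res3 <- synteny_maintenance(pool[1:40], pool[41:500], min_species = 5,
                              n_resamples = 500, seed = 3)
  expect_gt(res3$p_value, 0.01)

  # pool smaller than the draw is capped and flagged
  res4 <- synteny_maintenance(rep(6L, 50), rep(6L, 20), n_resamples = 50,
                              seed = 4)
  expect_true(res4$capped)
})
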