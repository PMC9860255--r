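np_acrs <- function(starts, ends, chrom = "c1") {
  x <- gintervals(rep(chrom, length(starts)), starts, ends)
  x$acr_id <- sprintf("A%02d", seq_along(starts))
  x$acr_class <- "nonpromoter"
  x
}

test_that("clustering chains ACRs at gaps <= 49 bp and not at 50", {
  # gaps of 10 and 20: one cluster of three
  a <- np_acrs(c(0L, 110L, 230L), c(100L, 210L, 330L))
  cl <- cluster_nonpromoter_acrs(a)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_constituents, 3L)
  expect_equal(cl$length, 330L)

  # gap 49 chains, then gap 50 breaks
  b <- np_acrs(c(0L, 149L, 299L), c(100L, 249L, 399L))
  cl2 <- cluster_nonpromoter_acrs(b, max_gap = 49)
  expect_equal(cl2$n_constituents, c(2L, 1L))

  # promoter ACRs are ignored
  b$acr_class[1] <- "promoter"
  cl3 <- cluster_nonpromoter_acrs(b)
  expect_equal(sum(cl3$n_constituents), 2L)
})

test_that("clustering equals the brute-force chaining oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:120, 1)
    a <- random_intervals(n)
    a$acr_id <- sprintf("A%03d", seq_len(n))
    a$acr_class <- "nonpromoter"
    cl <- cluster_nonpromoter_acrs(a, max_gap = 49)
    want <- oracle_merge(a, max_gap = 50)   # gap <= 49 merges
    expect_equal(cl$start, want$start)
    expect_equal(cl$end, want$end)
    expect_equal(sum(cl$n_constituents), n)
  }
})

clusters_of_lengths <- function(lens) {
  start <- cumsum(c(0L, head(lens, -1) + 1000L))
  data.frame(cluster_id = sprintf("CL%03d", seq_along(lens)), chrom = "c1",
             start = start, end = start + lens, length = lens,
             n_constituents = 1L, constituent_ids = "x",
             stringsAsFactors = FALSE)
}

test_that("SE selection takes the ceiling of the top fraction", {
  set.seed(9)
  cl <- clusters_of_lengths(sample(200:3000, 200))
  sel <- select_super_enhancers(cl, top_fraction = 0.025)
  expect_equal(nrow(sel$ses), 5L)  # ceiling(0.025 * 200)
  # equals the sort oracle
  expect_equal(sort(sel$ses$length, decreasing = TRUE),
               sort(cl$length, decreasing = TRUE)[1:5])
  expect_equal(sel$se_length_threshold, sort(cl$length, decreasing = TRUE)[5])

  # 40 clusters -> k = 1, the single longest
  cl40 <- clusters_of_lengths(sample(200:3000, 40))
  sel40 <- select_super_enhancers(cl40, 0.025)
  expect_equal(nrow(sel40$ses), 1L)
  expect_equal(sel40$ses$length, max(cl40$length))

  # all equal lengths: first k in coordinate order
  eq <- clusters_of_lengths(rep(500L, 80))
  seleq <- select_super_enhancers(eq, 0.025)
  expect_equal(nrow(seleq$ses), 2L)
  expect_equal(seleq$ses$start, eq$start[1:2])
  expect_equal(seleq$se_length_threshold, 500L)

  expect_error(select_super_enhancers(cl, top_fraction = 0), "top_fraction")
  expect_error(select_super_enhancers(cl, top_fraction = 1), "top_fraction")
})

test_that("the realized length threshold is non-increasing in top_fraction", {
  set.seed(10)
  cl <- clusters_of_lengths(sample(200:3000, 150))
  fr <- c(0.01, 0.025, 0.05, 0.2, 0.5)
  thr <- vapply(fr, function(f)
    select_super_enhancers(cl, f)$se_length_threshold, numeric(1))
  expect_true(all(diff(thr) <= 0))
})

test_that("length mode selects every cluster above the bp threshold", {
  cl <- clusters_of_lengths(c(400L, 1500L, 1499L, 2600L))
  sel <- select_super_enhancers(cl, mode = "length", min_length = 1500)
  expect_equal(sort(sel$ses$length), c(1500L, 2600L))
  expect_equal(sel$se_length_threshold, 1500L)
})

test_that("cognate gene assignment minimizes distance with TSS tie-break", {
  gm <- toy_genes()  # GA [1000,3000)+, GB [6000,8000)-
  ses <- data.frame(se_id = c("S1", "S2", "S3"), chrom = "c1",
                    start = c(1500L, 3100L, 4450L),
                    end = c(1800L, 3400L, 4550L), stringsAsFactors = FALSE)
  # S3 midpoint 4500 is equidistant (1500) from both gene bodies:
  # |4500 - tss(GA)=1000| = 3500 > |4500 - tss(GB)=8000| = 3500 -> tie again,
  # falls to lexicographic gene_id
  got <- assign_cognate_gene(ses, gm)
  expect_equal(got$cognate_gene, c("GA", "GA", "GA"))
  expect_equal(got$cognate_distance, c(0L, 100L, 1450L))

  # gene-free chromosome: flagged with NA
  ses2 <- data.frame(se_id = "S9", chrom = "c9", start = 0L, end = 100L)
  got2 <- assign_cognate_gene(ses2, gm)
  expect_true(is.na(got2$cognate_gene))

  # brute force over all genes for random cases
  set.seed(4)
  for (i in 1:20) {
    st <- sample.int(10000, 1)
    se <- data.frame(se_id = "S", chrom = "c1", start = st, end = st + 200L)
    got <- assign_cognate_gene(se, gm)
    d <- vapply(seq_len(2), function(k) {
      g <- gm$genes[k, ]
      max(g$start - se$end, se$start - g$end, 0L)
    }, numeric(1))
    expect_equal(got$cognate_distance, as.integer(min(d)))
  }
})

test_that("SE position classes follow the majority-overlap and containment rules", {
  g <- gene_models(
    data.frame(gene_id = c("G1", "G2", "G3"), chrom = "c1",
               start = c(1000L, 20000L, 30000L), end = c(10000L, 24000L, 34000L),
               strand = c("+", "+", "-"), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("G1", "G1", "G2", "G3"), chrom = "c1",
                       start = c(1000L, 8000L, 20000L, 30000L),
                       end = c(3000L, 10000L, 24000L, 34000L)))
  ses <- data.frame(
    se_id = c("SI", "SE", "SM", "SG", "SP"), chrom = "c1",
    start = c(4000L, 21000L, 2500L, 25000L, 11000L),
    end = c(6000L, 22000L, 8500L, 27000L, 13000L),
    stringsAsFactors = FALSE)
  got <- classify_se_position(ses, g)
  expect_equal(got$position_class[1], "genic_single_intron") # inside G1 intron
  expect_equal(got$position_class[2], "genic_exonic")        # inside G2 exon
  expect_equal(got$position_class[3], "genic_multifeature")  # spans exon+intron
  expect_equal(got$position_class[4], "intergenic")
  # between G2 (+, 3' end at 24000) and G3 (-, 3' end at 30000): both 3' ends
  expect_equal(got$intergenic_subclass[4], "three_prime_of_both")
  # SP between G1 (+) and G2 (+): 5' of the right flank
  expect_equal(got$position_class[5], "intergenic")
  expect_equal(got$intergenic_subclass[5], "five_prime_of_a_flank")
  # nearest gene-end distance for SG: TTS of G2 at 24000 -> 1000
  expect_equal(got$nearest_end_distance[4], 1000L)
})

test_that("atlas summary reproduces exact integer arithmetic", {
  ses <- data.frame(se_id = sprintf("S%03d", 1:200), chrom = "c1",
                    start = seq(0L, by = 5000L, length.out = 200))
  ses$end <- ses$start + 2000L
  ses$position_class <- c(rep("genic_multifeature", 26),
                          rep("intergenic", 174))
  ses$nearest_end_distance <- rep(c(1000L, 5000L), 100)
  ses$n_constituents <- 5L
  sm <- summarize_atlas(ses = ses, se_length_threshold = 1500)
  expect_equal(sm$n_ses, 200L)
  expect_equal(sm$n_genic, 26L)
  expect_equal(sm$n_intergenic, 174L)
  expect_equal(sm$genic_percent, 13)
  expect_equal(sm$n_genic + sm$n_intergenic, sm$n_ses)
  expect_equal(sm$mean_se_length, 2000)
  expect_equal(sm$fraction_near_gene_end, 0.5)
})
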