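# Independent brute-force oracles used across the suite. These are written
# against the contracts only and share no code with the implementation.

# O(n^2) transitive-closure chaining: two intervals end up in the same
# merged interval iff connected through gaps < max_gap
oracle_merge <- function(df, max_gap) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      gap <- max(sub$start[j] - sub$end[i], sub$start[i] - sub$end[j])
      if (gap < max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      m <- roots == r
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(sub$start[m]), end = max(sub$end[m]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

random_intervals <- function(n, n_chrom = 2, max_pos = 10000, max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  gintervals(chrom = paste0("c", sample.int(n_chrom, n, replace = TRUE)),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE))
}

# exhaustive affine-gap Smith-Waterman best local score (gap of length L
# costs gap_open + L * gap_extend, matching the implementation's
# convention); O(nm) three-state DP, for short sequences only
oracle_sw_score <- function(q, t, match = 1, mismatch = -1,
                            gap_open = 2, gap_extend = 1) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # aligned pair state
  X <- matrix(NEG, n + 1, m + 1)    # gap in target (query consumed)
  Y <- matrix(NEG, n + 1, m + 1)    # gap in query
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (qc[i] == tc[j] && qc[i] != "N") match else mismatch
    M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                           X[i, j + 1] - gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                           Y[i + 1, j] - gap_extend)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions with a different base
mutate_k <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

# tiny two-gene annotation used by several unit tests
toy_genes <- function() {
  gene_models(data.frame(
    gene_id = c("GA", "GB"), chrom = "c1",
    start = c(1000L, 6000L), end = c(3000L, 8000L),
    strand = c("+", "-"), stringsAsFactors = FALSE))
}
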