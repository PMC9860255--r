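#' Build junction reference sequences for a known insertion
#'
#' Three references of length `2 * flank` each: the left joint (upstream
#' genomic flank + element 5' end), the right joint (element 3' end +
#' downstream genomic flank), and the cross joint (upstream flank +
#' downstream flank, element absent).
#'
#' @param genome a [genome_index()] with sequence, for the haplotype
#'   WITHOUT the element (flanks are adjacent at `insertion_point`).
#' @param element_seq the inserted element's sequence (length >= `flank`).
#' @param chrom chromosome of the insertion.
#' @param insertion_point 0-based position where the element inserts
#'   (between `insertion_point - 1` and `insertion_point`).
#' @param flank flank length, bp (default 200).
#' @return List of class `junction_set`: `left_joint`, `right_joint`,
#'   `cross_joint` (uppercase strings), `flank`.
#' @export
build_junctions <- function(genome, element_seq, chrom, insertion_point,
                            flank = 200L) {
  flank <- as.integer(flank)
  if (flank <= 0) stop("flank must be > 0")
  el <- toupper(as.character(element_seq))
  if (nchar(el) < flank)
    stop("element shorter than flank; degenerate junction set rejected")
  len <- genome$seqlengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  if (insertion_point - flank < 0 || insertion_point + flank > len)
    stop("flank extends past chromosome end")
  up <- genome_sequence(genome, chrom, insertion_point - flank, insertion_point)
  down <- genome_sequence(genome, chrom, insertion_point, insertion_point + flank)
  out <- list(left_joint = paste0(up, substr(el, 1L, flank)),
              right_joint = paste0(substr(el, nchar(el) - flank + 1L, nchar(el)),
                                   down),
              cross_joint = paste0(up, down),
              flank = flank)
  class(out) <- "junction_set"
  out
}

# 0-based start positions where `read` matches `ref` with <= max_mismatch
# mismatches, trying the read as given and reverse-complemented
match_positions <- function(read, ref, max_mismatch = 2L) {
  hit_ranges <- function(seq) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(seq),
                                  Biostrings::DNAString(ref),
                                  max.mismatch = max_mismatch)
    if (length(m) == 0) return(NULL)
    data.frame(start = Biostrings::start(m) - 1L, end = Biostrings::end(m))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  out <- rbind(hit_ranges(read), if (rc != read) hit_ranges(rc))
  out
}

#' Count read pairs spanning each junction
#'
#' A pair spans a junction iff both mates align fully within that junction
#' reference (exact or up to `max_mismatch` mismatches, either
#' orientation) with the two mates on opposite sides of the joint midpoint
#' (one mate entirely in the left half, the other entirely in the right
#' half).
#'
#' @param read_pairs data.frame with `mate1` and `mate2` sequence columns.
#' @param junctions a [build_junctions()] result.
#' @param max_mismatch mismatches allowed per mate (default 2).
#' @return List of class `insertion_evidence`: `n_left`, `n_right`,
#'   `n_cross`.
#' @export
count_spanning_pairs <- function(read_pairs, junctions, max_mismatch = 2L) {
  mid <- junctions$flank
  spans <- function(m1, m2, ref) {
    h1 <- match_positions(m1, ref, max_mismatch)
    h2 <- match_positions(m2, ref, max_mismatch)
    if (is.null(h1) || is.null(h2)) return(FALSE)
    left1 <- any(h1$end <= mid); right1 <- any(h1$start >= mid)
    left2 <- any(h2$end <= mid); right2 <- any(h2$start >= mid)
    (left1 && right2) || (left2 && right1)
  }
  counts <- c(left_joint = 0L, right_joint = 0L, cross_joint = 0L)
  for (i in seq_len(nrow(read_pairs))) {
    for (j in names(counts)) {
      if (spans(read_pairs$mate1[i], read_pairs$mate2[i], junctions[[j]]))
        counts[j] <- counts[j] + 1L
    }
  }
  out <- list(n_left = unname(counts["left_joint"]),
              n_right = unname(counts["right_joint"]),
              n_cross = unname(counts["cross_joint"]))
  class(out) <- "insertion_evidence"
  out
}

#' Call insertion presence/absence from junction evidence
#'
#' Present iff at least `min_pairs` pairs span BOTH the left and the right
#' joint and none spans the cross joint; absent iff at least `min_pairs`
#' pairs span the cross joint and none spans either insertion joint; every
#' other pattern (including mixed, heterozygous-like evidence) is
#' ambiguous.
#'
#' @param evidence an `insertion_evidence` (or list/vector with `n_left`,
#'   `n_right`, `n_cross`).
#' @param min_pairs evidence threshold (default 4).
#' @return List of class `genotype_call`: `call` (`"present"`,
#'   `"absent"` or `"ambiguous"`) and `evidence`.
#' @export
classify_insertion <- function(evidence, min_pairs = 4L) {
  nl <- evidence$n_left; nr <- evidence$n_right; nc <- evidence$n_cross
  if (any(c(nl, nr, nc) < 0)) stop("negative evidence counts")
  call <- if (nl >= min_pairs && nr >= min_pairs && nc == 0) "present"
  else if (nc >= min_pairs && nl == 0 && nr == 0) "absent"
  else "ambiguous"
  structure(list(call = call,
                 evidence = list(n_left = nl, n_right = nr, n_cross = nc),
                 min_pairs = as.integer(min_pairs)),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("insertion call: %s (left %d, right %d, cross %d; min_pairs %d)\n",
              x$call, x$evidence$n_left, x$evidence$n_right,
              x$evidence$n_cross, x$min_pairs))
  invisible(x)
}
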