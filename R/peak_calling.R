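#' Parameters for kernel-density peak calling
#'
#' Defaults reimplement a Gaussian-kernel density peak caller in the F-seq
#' mould: bandwidth 60 bp (kernel SD), density evaluated every 10 bp, peaks
#' are maximal runs above `threshold` at least `min_peak_length` bp long,
#' and retention uses an empirical FDR computed from uniform-random null
#' libraries of the same depth. The canonical genome-scale configuration
#' uses 10,000 null replicates at FDR < 0.001; desk-scale analyses get
#' stable thresholds from far fewer replicates.
#'
#' @param bandwidth Gaussian kernel standard deviation, bp.
#' @param grid_step density grid spacing, bp.
#' @param threshold density threshold (reads per bp) for segmentation.
#' @param min_peak_length minimum peak length, bp.
#' @param fdr_target empirical FDR ceiling for retained peaks.
#' @param n_null_reps number of uniform null libraries.
#' @param seed integer seed for the null libraries.
#' @return List of class `peak_call_params`.
#' @export
peak_call_params <- function(bandwidth = 60, grid_step = 10, threshold = 0.02,
                             min_peak_length = 50, fdr_target = 0.001,
                             n_null_reps = 50L, seed = 1L) {
  stopifnot(bandwidth > 0, grid_step > 0, min_peak_length >= 0,
            fdr_target > 0, fdr_target < 1, n_null_reps >= 1)
  structure(list(bandwidth = bandwidth, grid_step = grid_step,
                 threshold = threshold, min_peak_length = min_peak_length,
                 fdr_target = fdr_target, n_null_reps = as.integer(n_null_reps),
                 seed = as.integer(seed)),
            class = "peak_call_params")
}

#' A read-start track for one chromosome of one sample
#'
#' @param chrom chromosome name.
#' @param positions sorted 0-based read 5' positions.
#' @param chrom_length chromosome length in bp.
#' @param total_mapped_reads total mapped reads in the whole sample
#'   (defaults to `length(positions)`).
#' @return List of class `read_start_track`.
#' @export
read_start_track <- function(chrom, positions, chrom_length,
                             total_mapped_reads = length(positions)) {
  positions <- sort(as.integer(positions))
  if (length(positions) && (positions[1] < 0 || positions[length(positions)] >= chrom_length))
    stop("read positions outside chromosome length")
  if (total_mapped_reads < length(positions))
    stop("total_mapped_reads smaller than number of positions")
  structure(list(chrom = chrom, positions = positions,
                 chrom_length = as.integer(chrom_length),
                 total_mapped_reads = as.integer(total_mapped_reads)),
            class = "read_start_track")
}

#' Gaussian kernel density of read starts on a uniform grid
#'
#' `density(x) = sum_i dnorm(x; p_i, bandwidth)`, truncated at +/- 4
#' bandwidths, so the integrated density (`sum * grid_step`) equals the
#' number of reads to within the truncation error (< 1%).
#'
#' @param track a [read_start_track()].
#' @param bandwidth kernel SD, bp.
#' @param grid_step grid spacing, bp.
#' @return List with `pos` (grid positions, bp) and `density`.
#' @export
kde_density <- function(track, bandwidth = 60, grid_step = 10) {
  p <- track$positions
  if (length(p) == 0) stop("empty read-start track")
  grid <- seq(0L, track$chrom_length - 1L, by = as.integer(grid_step))
  n_grid <- length(grid)
  halfw <- ceiling(4 * bandwidth / grid_step)
  # accumulate each read's truncated kernel over nearby grid cells
  k0 <- as.integer(floor(p / grid_step)) - halfw + 1L
  width <- 2L * halfw + 1L
  idx <- rep(k0, each = width) + rep.int(0:(width - 1L), length(p))
  ok <- idx >= 1L & idx <= n_grid
  xs <- grid[pmin(pmax(idx, 1L), n_grid)]
  vals <- stats::dnorm(xs - rep(p, each = width), sd = bandwidth)
  vals[!ok] <- 0
  idx[!ok] <- 1L
  dens <- numeric(n_grid)
  acc <- rowsum(vals, idx)
  dens[as.integer(rownames(acc))] <- acc[, 1]
  list(chrom = track$chrom, pos = grid, density = dens, grid_step = grid_step)
}

#' Segment a density profile into peaks
#'
#' Maximal runs of grid points with density >= `threshold` become peaks;
#' runs spanning less than `min_peak_length` bp are dropped. The summit is
#' the grid position of the run maximum and the score its density.
#'
#' @param dens output of [kde_density()].
#' @param threshold positive density threshold.
#' @param min_peak_length minimum peak length, bp.
#' @return Interval table with `summit` and `score` columns.
#' @export
call_peaks <- function(dens, threshold, min_peak_length = 50) {
  if (threshold <= 0) stop("threshold must be > 0")
  above <- dens$density >= threshold
  if (!any(above)) {
    return(gintervals(character(0), integer(0), integer(0),
                      summit = integer(0), score = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  step <- dens$grid_step
  out <- lapply(runs, function(i) {
    i1 <- starts[i]; i2 <- ends[i]
    s <- dens$pos[i1]
    e <- dens$pos[i2] + step          # half-open, one grid cell per point
    if (e - s < min_peak_length) return(NULL)
    j <- i1 + which.max(dens$density[i1:i2]) - 1L
    data.frame(chrom = dens$chrom, start = s, end = as.integer(e),
               strand = "*", summit = dens$pos[j],
               score = dens$density[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(gintervals(character(0), integer(0), integer(0),
                      summit = integer(0), score = numeric(0)))
  }
  out
}

#' Call peaks and retain them at an empirical FDR
#'
#' For each null replicate the same number of reads is placed uniformly at
#' random on the chromosome and peaks are called with identical parameters.
#' `FDR(s)` is the mean null count of peaks scoring >= s divided by the
#' observed count scoring >= s, regularized to be non-increasing in s by a
#' running minimum from high scores. The retained set is all observed peaks
#' with score >= the smallest threshold s achieving `FDR(s) < fdr_target`.
#'
#' @param track a [read_start_track()].
#' @param params a [peak_call_params()].
#' @return List with `peaks` (retained), `all_peaks`, `score_threshold`,
#'   `fdr_curve` (data.frame score/fdr), and `warning` (NULL or message when
#'   no score achieves the target and the retained set is empty).
#' @export
empirical_fdr_retain <- function(track, params) {
  obs <- call_peaks(kde_density(track, params$bandwidth, params$grid_step),
                    params$threshold, params$min_peak_length)
  empty <- obs[0, , drop = FALSE]
  if (nrow(obs) == 0) {
    return(list(peaks = empty, all_peaks = obs, score_threshold = NA_real_,
                fdr_curve = data.frame(score = numeric(0), fdr = numeric(0)),
                warning = "no observed peaks"))
  }
  null_scores <- with_seed(params$seed, {
    unlist(lapply(seq_len(params$n_null_reps), function(r) {
      nt <- read_start_track(track$chrom,
                             sample.int(track$chrom_length, length(track$positions),
                                        replace = TRUE) - 1L,
                             track$chrom_length)
      pk <- call_peaks(kde_density(nt, params$bandwidth, params$grid_step),
                       params$threshold, params$min_peak_length)
      pk$score
    }))
  })
  s <- sort(unique(obs$score))
  n_obs <- vapply(s, function(th) sum(obs$score >= th), numeric(1))
  n_null <- vapply(s, function(th) sum(null_scores >= th), numeric(1)) /
    params$n_null_reps
  fdr <- pmin(1, n_null / n_obs)
  # running minimum from the highest score down enforces monotonicity
  fdr <- rev(cummin(rev(fdr)))
  curve <- data.frame(score = s, fdr = fdr)
  ok <- which(fdr < params$fdr_target)
  if (length(ok) == 0) {
    return(list(peaks = empty, all_peaks = obs, score_threshold = NA_real_,
                fdr_curve = curve,
                warning = sprintf("no score threshold reaches FDR < %g",
                                  params$fdr_target)))
  }
  thr <- s[min(ok)]
  list(peaks = obs[obs$score >= thr, , drop = FALSE], all_peaks = obs,
       score_threshold = thr, fdr_curve = curve, warning = NULL)
}

# run code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
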