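#' Build a genome index from chromosome lengths or a FASTA file
#'
#' @param x either a named integer vector of chromosome lengths, the path
#'   to a FASTA file, or a named [Biostrings::DNAStringSet] (sequences are
#'   kept in memory and exposed through [genome_sequence()]).
#' @return An object of class `genome_index` with fields `seqlengths` and,
#'   when built from sequence, `sequences` (a [Biostrings::DNAStringSet]).
#' @export
genome_index <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (is.null(names(x))) stop("sequences must be named")
    gi <- list(seqlengths = stats::setNames(Biostrings::width(x), names(x)),
               sequences = x)
    class(gi) <- "genome_index"
    return(gi)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    seqs <- Biostrings::readDNAStringSet(x)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    gi <- list(seqlengths = stats::setNames(Biostrings::width(seqs), names(seqs)),
               sequences = seqs)
  } else {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("chromosome lengths must be named")
    gi <- list(seqlengths = stats::setNames(as.integer(x), names(x)),
               sequences = NULL)
  }
  class(gi) <- "genome_index"
  gi
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$seqlengths), "chromosome(s),",
      sum(as.numeric(x$seqlengths)), "bp",
      if (is.null(x$sequences)) "(lengths only)" else "(with sequence)", "\n")
  invisible(x)
}

#' Extract uppercase sequence for an interval
#'
#' @param genome a [genome_index()] built from FASTA.
#' @param chrom,start,end interval in 0-based half-open coordinates.
#' @return Character scalar over A/C/G/T/N.
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  if (is.null(genome$sequences)) stop("genome_index has no sequence data")
  len <- unname(genome$seqlengths[chrom])
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > len || end <= start)
    stop("interval [", start, ",", end, ") out of bounds for ", chrom)
  toupper(as.character(Biostrings::subseq(genome$sequences[[chrom]],
                                          start + 1L, end)))
}

#' Read gene models from a GFF3 file
#'
#' Reads `gene` and `exon` features, converting GFF3 1-based closed
#' coordinates to the package's 0-based half-open convention. TSS and TTS
#' are the strand-aware 5' and 3' boundary coordinates of the gene body.
#'
#' @param path GFF3 file.
#' @return A `gene_models` object: list with `genes` (gene_id, chrom, start,
#'   end, strand, tss, tts) and `exons` (gene_id, chrom, start, end).
#' @export
read_gff3_genes <- function(path) {
  gff <- rtracklayer::readGFF(path,
                              columns = c("seqid", "start", "end", "strand", "type"),
                              tags = c("ID", "Parent"))
  gff <- as.data.frame(gff)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    return(gene_models(genes = data.frame(gene_id = character(), chrom = character(),
                                          start = integer(), end = integer(),
                                          strand = character()),
                       exons = data.frame(gene_id = character(), chrom = character(),
                                          start = integer(), end = integer())))
  }
  gdf <- data.frame(gene_id = as.character(genes$ID),
                    chrom = as.character(genes$seqid),
                    start = genes$start - 1L,
                    end = as.integer(genes$end),
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  ex <- gff[gff$type == "exon", , drop = FALSE]
  parent <- vapply(ex$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
                   character(1))
  # exons point at mRNA parents; map mRNA -> gene
  mrna <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrna) > 0) {
    m2g <- stats::setNames(
      vapply(mrna$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
             character(1)),
      as.character(mrna$ID))
    mapped <- m2g[parent]
    parent <- ifelse(is.na(mapped), parent, mapped)
  }
  edf <- data.frame(gene_id = unname(parent),
                    chrom = as.character(ex$seqid),
                    start = ex$start - 1L,
                    end = as.integer(ex$end),
                    stringsAsFactors = FALSE)
  gene_models(genes = gdf, exons = edf)
}

#' Construct a gene_models object
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open; strand mandatory, `+` or `-`).
#' @param exons optional data.frame with `gene_id`, `chrom`, `start`, `end`;
#'   exons must be contained in their gene body.
#' @return List of class `gene_models` with `genes` (including computed
#'   `tss`, `tts` boundary coordinates) and `exons` sorted within gene.
#' @export
gene_models <- function(genes, exons = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad))
    stop("gene(s) without strand: ", paste(genes$gene_id[bad], collapse = ", "))
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  # tss/tts as half-open boundary coordinates: '+' genes start transcription
  # at `start`, '-' genes at `end`
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  if (is.null(exons)) {
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer())
  } else {
    exons <- exons[, c("gene_id", "chrom", "start", "end")]
    exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
    exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
    g <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(is.na(g$gene_id)))
      stop("exon with unknown gene_id")
    if (any(exons$start < g$start | exons$end > g$end))
      stop("exon outside its gene body")
  }
  out <- list(genes = genes, exons = exons)
  class(out) <- "gene_models"
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

# introns of one gene as an interval table (possibly empty)
gene_introns <- function(gm, gene_id) {
  ex <- gm$exons[gm$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) < 2) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  ex <- ex[order(ex$start), ]
  data.frame(chrom = ex$chrom[-1],
             start = ex$end[-nrow(ex)],
             end = ex$start[-1],
             stringsAsFactors = FALSE)
}

#' Strand-aware promoter windows upstream of each TSS
#'
#' For `+` genes the window is `[tss - upstream_bp, tss)`; for `-` genes it
#' is `[tss, tss + upstream_bp)` (upstream is rightward). The TSS base
#' itself is excluded in both cases. Windows are clipped at chromosome
#' start (position 0).
#'
#' @param gm a [gene_models()] object.
#' @param upstream_bp window size in bp (default 500).
#' @return Interval table with a `gene_id` column.
#' @export
promoter_windows <- function(gm, upstream_bp = 500L) {
  g <- gm$genes
  start <- ifelse(g$strand == "+", pmax(0L, g$tss - as.integer(upstream_bp)), g$tss)
  end <- ifelse(g$strand == "+", g$tss, g$tss + as.integer(upstream_bp))
  keep <- end > start
  gintervals(g$chrom[keep], start[keep], end[keep], g$strand[keep],
             gene_id = g$gene_id[keep])
}

#' Read a BED3/BED6 file into an interval table
#'
#' @param path BED file (no header).
#' @return Interval table; BED6 name/score/strand columns are kept when
#'   present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:max(3, count_fields(path))],
                          fill = TRUE)
  if (!"strand" %in% names(df)) df$strand <- "*"
  df$strand[is.na(df$strand) | df$strand == "."] <- "*"
  validate_gintervals(df)
  df
}

count_fields <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(3L)
  length(strsplit(first, "\t", fixed = TRUE)[[1]])
}

#' Write an interval table as BED6
#'
#' @param x interval table; optional `name` and `score` columns are used
#'   when present.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  validate_gintervals(x)
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = if ("name" %in% names(x)) x$name else ".",
                    score = if ("score" %in% names(x)) x$score else 0,
                    strand = if ("strand" %in% names(x))
                      ifelse(x$strand == "*", ".", x$strand) else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data.frame as headered TSV
#' @param x data.frame. @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV
#' @param path input file.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
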