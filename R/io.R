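#' Write and read the standard on-disk formats
#'
#' The simulator and pipeline exchange data through plain-text standard
#' formats: FASTA for the genome, GFF3 (1-based inclusive) for gene models,
#' bedGraph (0-based half-open) for coverage, BED6 for called peaks and TSV
#' for tables. Genome and annotation I/O goes through Biostrings and
#' rtracklayer.
#'
#' @name fnrscape-io
NULL

#' @describeIn fnrscape-io write the genome FASTA.
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @describeIn fnrscape-io read a genome FASTA.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @describeIn fnrscape-io write the gene panel as GFF3 (1-based inclusive).
#' @param panel gene panel data.frame (see [generate_genome()]).
#' @param genome_length contig length, recorded in the sequence-region
#'   directive.
#' @export
write_panel_gff3 <- function(panel, path, genome_length = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = panel$contig,
    ranges = IRanges::IRanges(panel$start, panel$end),
    strand = panel$strand,
    type = "gene",
    ID = panel$gene_id,
    regulatory_class = panel$class,
    regulatory_mode = panel$mode
  )
  if (!is.null(genome_length)) {
    GenomeInfoDb::seqlengths(gr) <- setNames(as.integer(genome_length),
                                             unique(panel$contig))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @describeIn fnrscape-io read a gene panel written by [write_panel_gff3()].
#' @export
read_panel_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  strand <- as.character(BiocGenerics::strand(gr))
  start <- BiocGenerics::start(gr)
  end <- BiocGenerics::end(gr)
  data.frame(
    gene_id = gr$ID,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = start, end = end, strand = strand,
    tss = as.integer(ifelse(strand == "+", start, end)),
    class = gr$regulatory_class %||% rep("constitutive", length(gr)),
    mode = gr$regulatory_mode %||% rep("none", length(gr)),
    stringsAsFactors = FALSE
  )
}

#' @describeIn fnrscape-io write a coverage track as 4-column bedGraph
#'   (0-based half-open); zero-coverage runs are written too so the contig
#'   length survives a round trip.
#' @param track a [coverage_track()].
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$coverage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  df <- data.frame(chrom = track$contig, start = starts, end = ends,
                   score = r$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn fnrscape-io read a bedGraph into a [coverage_track()].
#' @param contig_length optional; defaults to the largest end coordinate.
#' @export
read_bedgraph <- function(path, contig_length = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  contig <- as.character(GenomicRanges::seqnames(gr))[1]
  L <- contig_length %||% max(BiocGenerics::end(gr))
  cov <- integer(L)
  s <- BiocGenerics::start(gr)   # rtracklayer converts to 1-based
  e <- BiocGenerics::end(gr)
  v <- gr$score
  for (i in seq_along(s)) if (v[i] != 0) cov[s[i]:e[i]] <- v[i]
  coverage_track(contig, cov)
}

#' @describeIn fnrscape-io write called peaks as BED6 plus a detail TSV.
#'   BED scores are `-10 * log10(p)` capped at 1000.
#' @param peaks peak data.frame from [call_peaks()].
#' @param factor factor label used as the BED name field.
#' @export
write_peaks_bed <- function(peaks, path, factor = "peak") {
  score <- pmin(round(-10 * log10(pmax(peaks$p, 1e-300))), 1000)
  bed <- data.frame(chrom = peaks$contig, start = peaks$start,
                    end = peaks$end,
                    name = rep(factor, nrow(peaks)), score = score,
                    strand = rep(".", nrow(peaks)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' @describeIn fnrscape-io write a count matrix with gene ids in the first
#'   column; column names encode strain, condition and replicate
#'   (`WT_C_1`, ...).
#' @param counts integer matrix, genes x samples.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @describeIn fnrscape-io read a count matrix written by
#'   [write_counts_tsv()]; sample metadata is recovered from the column
#'   names.
#' @return `read_counts_tsv` returns a list with `counts` and `samples` as
#'   in [simulate_counts()].
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  parts <- strsplit(colnames(counts), "_")
  samples <- data.frame(
    sample = colnames(counts),
    strain = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, `[`, "", 2L),
    replicate = as.integer(vapply(parts, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  list(counts = counts, samples = samples)
}

#' @describeIn fnrscape-io write window sequences as FASTA.
#' @param seqs named character vector or DNAStringSet.
#' @export
write_windows_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
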