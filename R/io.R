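## File-format helpers. All standard formats go through Biostrings /
## rtracklayer; reads are handled in long character vectors because the QC
## filters are plain vectorised string operations.

#' Read a FASTQ file into a data frame
#' @param path FASTQ file, optionally gzipped (Phred+33).
#' @return data.frame with character columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL)
}

#' Write reads to FASTQ
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output path; gzipped when it ends in `.gz`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#' @param seqs named character vector (DNA or RNA).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## gene models -------------------------------------------------------------

#' Convert the generator's gene table to GRanges and write GFF3
#' @param gff data.frame with columns seqid, type (gene/exon), start, end,
#'   strand, ID, Parent.
#' @param path output `.gff3` path.
#' @export
write_gff3 <- function(gff, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gff$seqid,
    ranges = IRanges::IRanges(gff$start, gff$end),
    strand = gff$strand
  )
  S4Vectors::mcols(gr)$type <- gff$type
  S4Vectors::mcols(gr)$ID <- gff$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(gff$Parent), NA, gff$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 into the internal gene table layout
#' @param path `.gff3` file with `gene` and `exon` features.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- S4Vectors::mcols(gr)$Parent
  parent_chr <- vapply(seq_along(gr), function(i) {
    p <- parent[[i]]
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = as.character(S4Vectors::mcols(gr)$ID),
    Parent = parent_chr,
    row.names = NULL
  )
}

#' Write genomic intervals as BED (0-based half-open)
#' @param intervals data.frame with seqid, start, end (1-based inclusive)
#'   and optional name.
#' @param path output `.bed` path.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(intervals$seqid,
                               IRanges::IRanges(intervals$start,
                                                intervals$end))
  names(gr) <- if (!is.null(intervals$name)) intervals$name else
    paste0("iv", seq_len(nrow(intervals)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BED intervals into 1-based inclusive coordinates
#' @param path `.bed` file.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = if (!is.null(names(gr))) names(gr) else NA,
             row.names = NULL)
}

#' Write a feature-by-library count matrix as TSV
#' @param counts integer matrix with feature rownames and library colnames.
#' @param path output path.
#' @param id_col name of the leading identifier column.
#' @export
write_counts <- function(counts, path, id_col = "feature") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   row.names = NULL)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#' @param path TSV with an identifier column followed by library columns.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
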