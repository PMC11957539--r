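#' @importFrom withr with_seed
NULL

# IUPAC nucleotide code -> base set, used by the motif classifier and the
# user-supplied pattern configs.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.complement_chr <- function(x) chartr("ACGTN", "TGCAN", x)

.revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(.complement_chr(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Integer index (1-based) -> fixed-width base-4 DNA word; used to draw
# collision-free UMIs.
.index_to_umi <- function(idx, width) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(idx), ncol = width)
  v <- idx - 1L
  for (j in seq_len(width)) {
    out[, width - j + 1L] <- bases[(v %% 4L) + 1L]
    v <- v %/% 4L
  }
  apply(out, 1L, paste, collapse = "")
}

.check_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1L)
    stop(sprintf("'%s' must be a positive count", name), call. = FALSE)
  as.integer(x)
}

# Transcript-strand sequence of length `len` starting at the 5' position
# `pos` (1-based genomic) on `strand` of chromosome string `chrom_seq`.
.transcript_seq <- function(chrom_seq, pos, strand, len) {
  if (strand == "+") {
    substr(chrom_seq, pos, pos + len - 1L)
  } else {
    .revcomp_chr(substr(chrom_seq, pos - len + 1L, pos))
  }
}

#' Write paired FASTQ files
#'
#' @param reads data.frame with \code{read_id}, \code{read1}, \code{read2},
#'   \code{qual1}, \code{qual2}.
#' @param fq1,fq2 output paths (plain text FASTQ).
#' @return invisibly, the two paths
#' @export
writeFastqPair <- function(reads, fq1, fq2) {
  q1 <- Biostrings::QualityScaledDNAStringSet(
    stats::setNames(Biostrings::DNAStringSet(reads$read1), reads$read_id),
    Biostrings::PhredQuality(stats::setNames(Biostrings::BStringSet(reads$qual1),
                                             reads$read_id)))
  q2 <- Biostrings::QualityScaledDNAStringSet(
    stats::setNames(Biostrings::DNAStringSet(reads$read2), reads$read_id),
    Biostrings::PhredQuality(stats::setNames(Biostrings::BStringSet(reads$qual2),
                                             reads$read_id)))
  Biostrings::writeQualityScaledXStringSet(q1, fq1)
  Biostrings::writeQualityScaledXStringSet(q2, fq2)
  invisible(c(fq1, fq2))
}

#' Read paired FASTQ files into a read table
#'
#' @param fq1,fq2 FASTQ paths
#' @return data.frame with \code{read_id}, \code{read1}, \code{read2},
#'   \code{qual1}, \code{qual2}
#' @export
readFastqPair <- function(fq1, fq2) {
  r1 <- Biostrings::readQualityScaledDNAStringSet(fq1)
  r2 <- Biostrings::readQualityScaledDNAStringSet(fq2)
  stopifnot(length(r1) == length(r2))
  data.frame(
    read_id = sub("\\s.*$", "", names(r1)),
    read1 = as.character(r1), read2 = as.character(r2),
    qual1 = as.character(Biostrings::quality(r1)),
    qual2 = as.character(Biostrings::quality(r2)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write TSS annotation as BED6
#'
#' BED is 0-based half-open; the name field is \code{gene_id|biotype}.
#'
#' @param reference a \code{ToyReference}
#' @param path output path
#' @return invisibly, the path
#' @export
writeAnnotationBed <- function(reference, path) {
  ann <- tssAnnotation(reference)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ann)),
    start = GenomicRanges::start(ann) - 1L,
    end = GenomicRanges::start(ann),
    name = paste(ann$gene_id, ann$biotype, sep = "|"),
    score = 0L,
    strand = as.character(GenomicRanges::strand(ann)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 TSS annotation
#'
#' @param path BED path with \code{gene_id|biotype} names
#' @return \code{GRanges} of 1-based single-nucleotide TSS positions
#' @export
readAnnotationBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  parts <- strsplit(df[[4]], "|", fixed = TRUE)
  GenomicRanges::GRanges(df[[1]],
    IRanges::IRanges(df[[2]] + 1L, df[[3]]), strand = df[[6]],
    gene_id = vapply(parts, `[`, "", 1L),
    biotype = vapply(parts, `[`, "", 2L))
}
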