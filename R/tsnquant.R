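#' Coverage thresholds for TSN calling
#'
#' Discovery tier requires 20 unique reads (quantification precision
#' 1/20 = 0.05); quantification tier requires 50 (precision 1/50 = 0.02).
#'
#' @param discovery_min minimum unique reads for a high-confidence TSN
#' @param quantify_min minimum unique reads for stoichiometry quantification
#' @return list of validated thresholds
#' @export
coverageThresholds <- function(discovery_min = 20L, quantify_min = 50L) {
  if (quantify_min < discovery_min)
    stop("quantify_min must be >= discovery_min", call. = FALSE)
  list(discovery_min = as.integer(discovery_min),
       quantify_min = as.integer(quantify_min))
}

#' Pile up deduplicated alignment 5' ends into TSN records
#'
#' Each unique molecule contributes one transcript-strand base call at its
#' transcription-start nucleotide: the first base of restored mate 1. For
#' plus-strand molecules the TSN genomic coordinate is the leftmost aligned
#' base; for minus-strand molecules it is the rightmost, and the
#' transcript-strand call is the complement of the reference-strand base at
#' that coordinate (the restored read already is the transcript strand).
#'
#' @param alignments deduplicated restored alignments
#'   (\code{\link{dedupAlignments}})
#' @param reference the \code{ToyReference} (for the reference TSN base)
#' @return \code{GRanges}, one range per (chrom, strand, position), with
#'   metadata columns \code{A}, \code{C}, \code{G}, \code{T},
#'   \code{coverage}, \code{tsn_base} (transcript-strand reference base) and
#'   \code{non_conversion} (A/(A+G), NA when A+G = 0)
#' @export
pileupTSN <- function(alignments, reference) {
  if (nrow(alignments) == 0L)
    return(GenomicRanges::GRanges())
  dt <- data.table::as.data.table(alignments)
  dt[, pos := ifelse(strand == "+", m1_start, m1_end)]
  dt[, call := substr(mate1, 1L, 1L)]
  counts <- dt[, list(
    A = sum(call == "A"), C = sum(call == "C"),
    G = sum(call == "G"), T = sum(call == "T")),
    by = c("chrom", "strand", "pos")]
  counts[, coverage := A + C + G + T]
  seqs <- as.character(refSeqs(reference))
  ref_base <- vapply(seq_len(nrow(counts)), function(i) {
    b <- substr(seqs[[counts$chrom[i]]], counts$pos[i], counts$pos[i])
    if (counts$strand[i] == "+") b else .complement_chr(b)
  }, character(1))
  counts[, tsn_base := ref_base]
  counts[, non_conversion := ifelse(A + G > 0, A / (A + G), NA_real_)]
  data.table::setorder(counts, chrom, pos, strand)
  GenomicRanges::GRanges(counts$chrom,
    IRanges::IRanges(counts$pos, counts$pos), strand = counts$strand,
    A = counts$A, C = counts$C, G = counts$G, T = counts$T,
    coverage = counts$coverage, tsn_base = counts$tsn_base,
    non_conversion = counts$non_conversion)
}

#' Non-conversion rate of a TSN record
#'
#' The m6Am stoichiometry estimator: A counts over A + G counts. C and T
#' calls are ignored in the ratio (they are counted in coverage). When
#' A + G = 0 the rate is undefined and \code{NA} is returned, distinct
#' from a true 0.
#'
#' @param A,G base call counts (vectors allowed)
#' @return rate(s) in [0,1], or NA where undefined
#' @examples
#' nonConversion(934, 66)   # 0.934
#' @export
nonConversion <- function(A, G) {
  ifelse(A + G > 0, A / (A + G), NA_real_)
}

#' Merge replicate TSN tables and assign coverage tiers
#'
#' Reads from biological/technical replicates are pooled per site before
#' quantification: base counts are summed, then the non-conversion rate is
#' recomputed from the pooled counts (a pooled-count ratio, not a mean of
#' per-replicate ratios). Sites are tiered by merged coverage:
#' \code{quantified} at >= quantify_min, \code{discovery} at
#' >= discovery_min, else \code{raw}. Reported precision is 1/coverage.
#'
#' @param tables list of per-replicate \code{GRanges} from
#'   \code{\link{pileupTSN}} (a single \code{GRanges} is accepted)
#' @param thresholds from \code{\link{coverageThresholds}}
#' @return merged \code{GRanges} with \code{tier} and \code{precision}
#'   metadata columns
#' @export
callAndMerge <- function(tables, thresholds = coverageThresholds()) {
  if (is(tables, "GRanges")) tables <- list(tables)
  if (!length(tables)) stop("no replicate tables", call. = FALSE)
  dfs <- lapply(tables, function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               strand = as.character(GenomicRanges::strand(gr)),
               pos = GenomicRanges::start(gr),
               A = gr$A, C = gr$C, G = gr$G, T = gr$T,
               tsn_base = gr$tsn_base, stringsAsFactors = FALSE)
  })
  ref_check <- lapply(dfs, function(d) d[, c("chrom", "strand", "pos",
                                             "tsn_base")])
  all_sites <- do.call(rbind, ref_check)
  if (anyDuplicated(all_sites[, 1:3])) {
    dup <- all_sites[duplicated(all_sites[, 1:3]) |
                     duplicated(all_sites[, 1:3], fromLast = TRUE), ]
    if (any(tapply(dup$tsn_base, paste(dup$chrom, dup$strand, dup$pos),
                   function(x) length(unique(x)) > 1L)))
      stop("replicates disagree on the reference base: mixed references",
           call. = FALSE)
  }
  dt <- data.table::as.data.table(do.call(rbind, dfs))
  merged <- dt[, list(A = sum(A), C = sum(C), G = sum(G), T = sum(T),
                      tsn_base = tsn_base[1L]),
               by = c("chrom", "strand", "pos")]
  merged[, coverage := A + C + G + T]
  merged[, non_conversion := ifelse(A + G > 0, A / (A + G), NA_real_)]
  merged[, tier := ifelse(coverage >= thresholds$quantify_min, "quantified",
                   ifelse(coverage >= thresholds$discovery_min, "discovery",
                          "raw"))]
  merged[, precision := 1 / coverage]
  data.table::setorder(merged, chrom, pos, strand)
  GenomicRanges::GRanges(merged$chrom,
    IRanges::IRanges(merged$pos, merged$pos), strand = merged$strand,
    A = merged$A, C = merged$C, G = merged$G, T = merged$T,
    coverage = merged$coverage, tsn_base = merged$tsn_base,
    non_conversion = merged$non_conversion, tier = merged$tier,
    precision = merged$precision)
}

#' Write TSN records as BED6+
#'
#' Columns: chrom, start (0-based), end, name (\code{gene|tsn_base}, or
#' \code{.} when unassigned), score (coverage), strand, then A, C, G, T
#' counts, non_conversion and tier.
#'
#' @param tsn \code{GRanges} of TSN records (gene assignment optional, in
#'   metadata column \code{gene_id})
#' @param path output path
#' @return invisibly, the path
#' @export
writeTsnBed <- function(tsn, path) {
  gene <- if (!is.null(tsn$gene_id)) tsn$gene_id else rep(".", length(tsn))
  gene[is.na(gene)] <- "."
  tier <- if (!is.null(tsn$tier)) tsn$tier else rep(NA_character_, length(tsn))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tsn)),
    start = GenomicRanges::start(tsn) - 1L,
    end = GenomicRanges::start(tsn),
    name = paste(gene, tsn$tsn_base, sep = "|"),
    score = tsn$coverage,
    strand = as.character(GenomicRanges::strand(tsn)),
    A = tsn$A, C = tsn$C, G = tsn$G, T = tsn$T,
    non_conversion = tsn$non_conversion, tier = tier)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
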