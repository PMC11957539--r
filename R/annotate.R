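BIOTYPE_PRIORITY <- c(snRNA = 1L, snoRNA = 2L, protein_coding = 3L,
                      lncRNA = 4L, other = 5L, spikein = 5L)

#' Assign TSNs to genes by nearest annotated TSS with biotype priority
#'
#' A TSN is assignable to a gene when an annotated TSS lies on the same
#' chromosome and strand within \code{max_distance} nt (inclusive). Among
#' eligible TSSs the gene is chosen by biotype priority
#' (snRNA > snoRNA > protein_coding > lncRNA > others), then by smallest
#' absolute distance, then by lexicographic gene id. Assignment is
#' deterministic and independent of input order.
#'
#' @param tsn \code{GRanges} of TSN records
#' @param annotation \code{GRanges} of single-nucleotide TSSs with
#'   \code{gene_id} and \code{biotype} (or a \code{ToyReference})
#' @param max_distance maximum |distance| in nt (default 100)
#' @return \code{tsn} with added metadata columns \code{gene_id} (NA when
#'   unassigned), \code{gene_biotype}, \code{tss_distance}
#' @export
assignGenes <- function(tsn, annotation, max_distance = 100L) {
  if (is(annotation, "ToyReference")) annotation <- tssAnnotation(annotation)
  tsn$gene_id <- NA_character_
  tsn$gene_biotype <- NA_character_
  tsn$tss_distance <- NA_integer_
  if (length(tsn) == 0L || length(annotation) == 0L) return(tsn)
  hits <- GenomicRanges::findOverlaps(tsn, annotation,
    maxgap = max_distance, ignore.strand = FALSE)
  if (length(hits) == 0L) return(tsn)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  d <- abs(GenomicRanges::start(tsn)[qh] - GenomicRanges::start(annotation)[sh])
  keep <- d <= max_distance
  qh <- qh[keep]; sh <- sh[keep]; d <- d[keep]
  if (length(qh) == 0L) return(tsn)
  pri <- BIOTYPE_PRIORITY[annotation$biotype[sh]]
  pri[is.na(pri)] <- 5L
  ord <- order(qh, pri, d, annotation$gene_id[sh])
  qh <- qh[ord]; sh <- sh[ord]; d <- d[ord]
  first <- !duplicated(qh)
  tsn$gene_id[qh[first]] <- annotation$gene_id[sh[first]]
  tsn$gene_biotype[qh[first]] <- annotation$biotype[sh[first]]
  tsn$tss_distance[qh[first]] <- d[first]
  tsn
}

#' Gene composition from summary fractions
#'
#' The worked-example arithmetic: given the percentage of a gene's
#' transcripts that initiate with A and the pooled non-conversion rate of
#' its A-TSNs, the transcript pool splits into
#' m6Am = A-fraction x non-conversion, Am = A-fraction x (1 -
#' non-conversion), and non-A = the remainder.
#'
#' @param a_fraction_pct percent of transcripts that are A-initiated
#' @param non_conversion pooled A-TSN non-conversion rate in [0,1]
#' @return named vector (percent): \code{pct_m6am}, \code{pct_am},
#'   \code{pct_nonA}
#' @examples
#' compositionFromFractions(54.0, 0.934)  # 50.4 / 3.6 / 46.0
#' @export
compositionFromFractions <- function(a_fraction_pct, non_conversion) {
  stopifnot(a_fraction_pct >= 0, a_fraction_pct <= 100,
            non_conversion >= 0, non_conversion <= 1)
  m6am <- a_fraction_pct * non_conversion
  am <- a_fraction_pct * (1 - non_conversion)
  c(pct_m6am = m6am, pct_am = am, pct_nonA = 100 - a_fraction_pct)
}

#' Per-gene m6Am summary from assigned TSN records
#'
#' Pools a gene's TSNs read-weighted: the m6Am percentage is
#' 100 x sum(A-site reads x site non-conversion) / total reads, the Am
#' percentage its complement over the A-initiated pool, and non-A the
#' remainder. The m6Am gene index is the read-weighted fraction of
#' transcription-start events that are m6Am-initiated
#' (\code{pct_m6am/100}); an unweighted per-site variant (mean site
#' stoichiometry over all sites, A sites only contributing) is available
#' with \code{weighted = FALSE}.
#'
#' @param tsn assigned \code{GRanges} (from \code{\link{assignGenes}});
#'   typically filtered to the quantified tier for stoichiometry terms
#' @param weighted read-weighted index (default) or per-site average
#' @return data.frame, one row per gene: \code{gene_id},
#'   \code{total_tsn_reads}, \code{a_tsn_reads}, \code{pct_m6am},
#'   \code{pct_am}, \code{pct_nonA}, \code{m6am_gene_index}
#' @export
geneComposition <- function(tsn, weighted = TRUE) {
  tsn <- tsn[!is.na(tsn$gene_id)]
  if (length(tsn) == 0L)
    return(data.frame(gene_id = character(0), total_tsn_reads = integer(0),
      a_tsn_reads = integer(0), pct_m6am = numeric(0), pct_am = numeric(0),
      pct_nonA = numeric(0), m6am_gene_index = numeric(0)))
  df <- data.frame(gene_id = tsn$gene_id, coverage = tsn$coverage,
                   A = tsn$A, G = tsn$G, tsn_base = tsn$tsn_base,
                   non_conversion = tsn$non_conversion,
                   stringsAsFactors = FALSE)
  dt <- data.table::as.data.table(df)
  dt[, is_a := tsn_base == "A"]
  out <- dt[, {
    total <- sum(coverage)
    a_reads <- sum(coverage[is_a])
    nc_ok <- is_a & !is.na(non_conversion)
    m6am_reads <- sum(coverage[nc_ok] * non_conversion[nc_ok])
    am_reads <- sum(coverage[nc_ok] * (1 - non_conversion[nc_ok]))
    idx <- if (weighted) {
      if (total > 0) m6am_reads / total else NA_real_
    } else {
      nc_site <- ifelse(is_a, ifelse(is.na(non_conversion), 0,
                                     non_conversion), 0)
      mean(nc_site)
    }
    list(total_tsn_reads = total, a_tsn_reads = a_reads,
         pct_m6am = 100 * m6am_reads / total,
         pct_am = 100 * am_reads / total,
         pct_nonA = 100 * (total - a_reads) / total,
         m6am_gene_index = idx)
  }, by = "gene_id"]
  as.data.frame(out[order(gene_id)])
}

#' Gene index table
#'
#' One row per gene with the m6Am gene index (the read-weighted ratio of
#' m6Am-initiated transcription-start events over all events), sorted by
#' index, suitable for joining against external per-gene measurements.
#'
#' @param summaries output of \code{\link{geneComposition}}
#' @return data.frame with \code{gene_id}, \code{m6am_gene_index},
#'   \code{total_tsn_reads}
#' @export
geneIndexTable <- function(summaries) {
  out <- summaries[, c("gene_id", "m6am_gene_index", "total_tsn_reads")]
  out[order(-out$m6am_gene_index, out$gene_id), , drop = FALSE]
}
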