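#' Build the read-body pileup of reference-A positions
#'
#' For every restored, deduplicated mate-1 alignment, tallies the read base
#' at each reference position whose transcript-strand base is A, excluding
#' the read's own transcription-start nucleotide (offset +1, which belongs
#' to the TSN pileup). This is the substrate for the GLORI-style internal
#' m6A caller.
#'
#' @param alignments deduplicated restored alignments; a \code{gene_id}
#'   column (e.g. inherited from the TSN assignment) is carried through
#' @param reference the \code{ToyReference}
#' @return list with \code{long} (read_id, gene_id, chrom, strand, pos,
#'   read_base -- one row per read x reference-A position) used for both
#'   the noise filter and the region flag
#' @export
internalPileup <- function(alignments, reference) {
  seqs <- as.character(refSeqs(reference))
  rows <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    len <- a$m1_end - a$m1_start + 1L
    refseq <- substr(seqs[[a$chrom]], a$m1_start, a$m1_end)
    if (a$strand == "-") refseq <- .revcomp_chr(refseq)
    rb <- strsplit(refseq, "", fixed = TRUE)[[1]]
    qb <- strsplit(a$mate1, "", fixed = TRUE)[[1]]
    offs <- which(rb == "A")
    offs <- offs[offs > 1L]  # exclude the TSN
    if (!length(offs)) next
    gpos <- if (a$strand == "+") a$m1_start + offs - 1L
            else a$m1_end - offs + 1L
    rows[[i]] <- data.frame(read_id = a$read_id,
      gene_id = if (!is.null(a$gene_id)) a$gene_id else NA_character_,
      chrom = a$chrom, strand = a$strand, pos = gpos,
      read_base = qb[offs], stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(long))
    long <- data.frame(read_id = character(0), gene_id = character(0),
      chrom = character(0), strand = character(0), pos = integer(0),
      read_base = character(0), stringsAsFactors = FALSE)
  list(long = long)
}

#' Read-level noise filter
#'
#' Reads carrying more than \code{max_nonconverted} (default 3)
#' non-converted A's in their body are treated as conversion failures and
#' discarded; exactly 3 is kept.
#'
#' @param long long pileup table from \code{\link{internalPileup}}
#' @param max_nonconverted threshold (default 3)
#' @return list with \code{long} (surviving rows), \code{discarded_reads},
#'   and \code{excluded_fraction}
#' @export
readNoiseFilter <- function(long, max_nonconverted = 3L) {
  if (nrow(long) == 0L)
    return(list(long = long, discarded_reads = character(0),
                excluded_fraction = 0))
  dt <- data.table::as.data.table(long)
  per_read <- dt[, list(n_nc = sum(read_base == "A")), by = "read_id"]
  bad <- per_read$read_id[per_read$n_nc > max_nonconverted]
  list(long = long[!long$read_id %in% bad, , drop = FALSE],
       discarded_reads = bad,
       excluded_fraction = length(bad) / nrow(per_read))
}

#' Gene-specific background non-conversion rate
#'
#' For each gene with at least \code{min_counts} (default 1000) A+G
#' observations over its reference-A body positions, the background is the
#' pooled non-conversion rate sum(A)/sum(A+G); genes below the count floor
#' are skipped with a \code{low_gene_coverage} flag.
#'
#' @param long (noise-filtered) long pileup table
#' @param min_counts minimum A+G observations per gene (default 1000)
#' @return data.frame: \code{gene_id}, \code{counts}, \code{background},
#'   \code{low_gene_coverage}
#' @export
geneBackground <- function(long, min_counts = 1000L) {
  dt <- data.table::as.data.table(long)
  dt <- dt[read_base %in% c("A", "G")]
  out <- dt[, list(counts = .N, a = sum(read_base == "A")), by = "gene_id"]
  out[, background := ifelse(counts >= min_counts, a / counts, NA_real_)]
  out[, low_gene_coverage := counts < min_counts]
  as.data.frame(out[, c("gene_id", "counts", "background",
                        "low_gene_coverage")])
}

#' One-sided binomial tail for excess non-conversion
#'
#' P(X >= a) with X ~ Binomial(a + g, background); the alternative of
#' interest is more non-conversion than the gene background explains.
#'
#' @param a,g A and G counts at the site
#' @param background gene background rate
#' @return upper-tail probability
#' @export
binomialTail <- function(a, g, background) {
  stats::pbinom(a - 1L, a + g, background, lower.tail = FALSE)
}

#' Call internal m6A sites with the filter cascade
#'
#' A site is called when, simultaneously: coverage (A+G) >=
#' \code{min_reads}; non-conversion strictly above \code{min_rate}; the
#' one-sided binomial tail against the gene background is below
#' \code{alpha}; and the site is not flagged as lying in a
#' conversion-resistant region (the pooled non-conversion of all other
#' reference-A positions inside the reads covering the site exceeds
#' \code{region_rate_cap}). Rejections carry reasons.
#'
#' @param long noise-filtered long pileup table
#' @param backgrounds from \code{\link{geneBackground}}
#' @param min_reads coverage floor (default 20)
#' @param min_rate rate must exceed this (default 0.1)
#' @param alpha binomial significance level (default 0.05)
#' @param region_rate_cap conversion-resistant-region cap (default 0.05)
#' @return data.frame, one row per candidate site: counts, rate,
#'   background, p-value, flags, \code{called}, \code{reason}
#' @export
callInternalM6A <- function(long, backgrounds, min_reads = 20L,
                            min_rate = 0.1, alpha = 0.05,
                            region_rate_cap = 0.05) {
  dt <- data.table::as.data.table(long)
  dt <- dt[read_base %in% c("A", "G")]
  sites <- dt[, list(a_count = sum(read_base == "A"),
                     g_count = sum(read_base == "G"),
                     gene_id = gene_id[1L]),
              by = c("chrom", "strand", "pos")]
  sites[, coverage := a_count + g_count]
  sites[, non_conversion := ifelse(coverage > 0, a_count / coverage,
                                   NA_real_)]
  bg <- backgrounds$background[match(sites$gene_id, backgrounds$gene_id)]
  sites[, background := bg]
  sites[, binomial_p := ifelse(is.na(background), NA_real_,
    binomialTail(a_count, g_count, background))]
  # conversion-resistant-region flag: pooled non-conversion of the OTHER
  # reference-A positions within the reads covering this site
  flag <- logical(nrow(sites))
  site_key <- paste(dt$chrom, dt$strand, dt$pos)
  keys <- paste(sites$chrom, sites$strand, sites$pos)
  reads_by_site <- split(dt$read_id, site_key)
  dt_by_read <- split(seq_len(nrow(dt)), dt$read_id)
  for (i in seq_len(nrow(sites))) {
    rids <- reads_by_site[[keys[i]]]
    rows <- unlist(dt_by_read[rids], use.names = FALSE)
    other <- dt[rows][!(chrom == sites$chrom[i] &
                        strand == sites$strand[i] & pos == sites$pos[i])]
    if (nrow(other)) {
      rate <- sum(other$read_base == "A") / nrow(other)
      flag[i] <- rate > region_rate_cap
    }
  }
  sites[, conversion_resistant_region := flag]
  sites[, low_gene_coverage := is.na(background)]
  reason_v <- rep(NA_character_, nrow(sites))
  called_v <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (sites$low_gene_coverage[i]) reason_v[i] <- "low_gene_coverage"
    else if (sites$coverage[i] < min_reads) reason_v[i] <- "low_coverage"
    else if (!(sites$non_conversion[i] > min_rate)) reason_v[i] <- "low_rate"
    else if (!(sites$binomial_p[i] < alpha)) reason_v[i] <- "not_significant"
    else if (sites$conversion_resistant_region[i])
      reason_v[i] <- "conversion_resistant_region"
    else called_v[i] <- TRUE
  }
  sites[, called := called_v]
  sites[, reason := reason_v]
  data.table::setorder(sites, chrom, pos, strand)
  as.data.frame(sites)
}

#' Average replicate non-conversion of called sites
#'
#' Replicate-level non-conversion rates of the same site are averaged after
#' calling.
#'
#' @param site_tables list of per-replicate call tables from
#'   \code{\link{callInternalM6A}}
#' @return data.frame of sites called in at least one replicate with the
#'   mean non-conversion across replicates reporting the site
#' @export
mergeInternalCalls <- function(site_tables) {
  all <- do.call(rbind, lapply(seq_along(site_tables), function(i) {
    x <- site_tables[[i]]; x$replicate <- i; x
  }))
  dt <- data.table::as.data.table(all)
  out <- dt[, list(
    non_conversion = mean(non_conversion),
    n_replicates = .N,
    called = any(called)), by = c("chrom", "strand", "pos")]
  as.data.frame(out[called == TRUE])
}
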