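#' TSN expression in transcription-start nucleotides per million
#'
#' \code{tpm_i = count_i / sum(count) * 1e6}; scale-invariant in the
#' library size.
#'
#' @param counts named numeric vector of per-TSN unique-molecule counts
#' @return data.frame with \code{tsn}, \code{raw_count}, \code{tpm}
#' @examples
#' calcTPM(c(s1 = 5, s2 = 5, s3 = 10))
#' @export
calcTPM <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("all-zero counts", call. = FALSE)
  data.frame(tsn = if (is.null(names(counts)))
               as.character(seq_along(counts)) else names(counts),
             raw_count = as.numeric(counts),
             tpm = as.numeric(counts) / total * 1e6,
             stringsAsFactors = FALSE)
}

#' Spike-in median-of-ratios scale factors
#'
#' Cross-sample calibration against spiked-in transcripts of constant
#' input: for each sample the factor is the median over spike-ins of
#' count / geometric-mean-across-samples (median-of-ratios restricted to
#' control rows). Dividing counts by the factors equalises spike-in
#' abundance across samples and is invariant to global library-size
#' multiplication.
#'
#' @param counts matrix (TSNs x samples) of unique-molecule counts with
#'   rownames
#' @param spikein_ids rownames of spike-in rows
#' @param min_spikeins minimum spike-ins with nonzero counts in every
#'   sample (default 3)
#' @return named numeric vector of per-sample scale factors
#' @export
spikeinScaleFactors <- function(counts, spikein_ids, min_spikeins = 3L) {
  sp <- counts[rownames(counts) %in% spikein_ids, , drop = FALSE]
  nonzero <- colSums(sp > 0)
  if (nrow(sp) < min_spikeins || any(nonzero < min_spikeins))
    stop("insufficient nonzero spike-in counts", call. = FALSE)
  use <- rowSums(sp > 0) == ncol(sp)
  sp <- sp[use, , drop = FALSE]
  if (nrow(sp) < min_spikeins)
    stop("insufficient spike-ins observed in every sample", call. = FALSE)
  loggeo <- rowMeans(log(sp))
  apply(sp, 2L, function(col)
    exp(stats::median((log(col) - loggeo)[is.finite(loggeo) & col > 0])))
}

#' Normalize a count matrix by spike-in scale factors
#'
#' @param counts matrix (TSNs x samples)
#' @param factors from \code{\link{spikeinScaleFactors}}
#' @return normalized count matrix
#' @export
normalizeCounts <- function(counts, factors) {
  sweep(counts, 2L, factors, "/")
}

#' Bin A-TSNs by m6Am stoichiometry
#'
#' Equal-count quantile bins ordered low to high stoichiometry, with
#' deterministic tie-breaking by site coordinate.
#'
#' @param non_conversion stoichiometry per site (no NAs)
#' @param n_bins number of bins (default 5)
#' @param chrom,pos optional coordinates for tie-breaking
#' @return integer bin labels in 1..n_bins (1 = lowest stoichiometry)
#' @export
binByStoichiometry <- function(non_conversion, n_bins = 5L,
                               chrom = NULL, pos = NULL) {
  if (any(is.na(non_conversion)))
    stop("non_conversion must be defined for all sites", call. = FALSE)
  n <- length(non_conversion)
  if (n < n_bins) stop("fewer sites than bins", call. = FALSE)
  if (is.null(chrom)) chrom <- rep("", n)
  if (is.null(pos)) pos <- seq_len(n)
  ord <- order(non_conversion, chrom, pos)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  bin
}

#' Differential TSN expression between two conditions
#'
#' Spike-in-normalized counts are compared with a Welch two-sided t-test on
#' \code{log2(normalized + 0.5)} across replicates; the fold change is
#' \code{log2((mean_B + 0.5) / (mean_A + 0.5))}. Only TSNs whose baseMean
#' (mean normalized count over all samples) reaches \code{min_base_mean}
#' are tested. Benjamini-Hochberg adjusted p-values are provided.
#'
#' @param norm_counts normalized matrix (TSNs x samples) with rownames
#' @param condition_a,condition_b column names (>= 2 replicates each)
#' @param min_base_mean baseMean filter (default 100)
#' @return data.frame: \code{tsn}, \code{base_mean},
#'   \code{log2_fold_change}, \code{p_value}, \code{padj}
#' @export
differentialTSN <- function(norm_counts, condition_a, condition_b,
                            min_base_mean = 100) {
  if (length(condition_a) < 2L || length(condition_b) < 2L)
    stop("need >= 2 replicates per condition", call. = FALSE)
  a <- norm_counts[, condition_a, drop = FALSE]
  b <- norm_counts[, condition_b, drop = FALSE]
  base_mean <- rowMeans(cbind(a, b))
  keep <- base_mean >= min_base_mean
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  la <- log2(a + 0.5); lb <- log2(b + 0.5)
  lfc <- log2((rowMeans(b) + 0.5) / (rowMeans(a) + 0.5))
  pv <- vapply(seq_len(nrow(a)), function(i) {
    va <- la[i, ]; vb <- lb[i, ]
    if (stats::var(va) == 0 && stats::var(vb) == 0)
      return(if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else NA_real_)
    stats::t.test(va, vb, var.equal = FALSE)$p.value
  }, numeric(1))
  data.frame(tsn = rownames(norm_counts)[keep],
             base_mean = base_mean[keep], log2_fold_change = lfc,
             p_value = pv, padj = stats::p.adjust(pv, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a count matrix and design table for external NB-GLM tools
#'
#' Adapter for users who want to run a negative-binomial GLM stack instead
#' of the built-in Welch test: writes the raw count matrix and a design
#' table (sample, condition) as TSV.
#'
#' @param counts matrix (TSNs x samples)
#' @param condition named or ordered condition labels per sample
#' @param dir output directory
#' @return invisibly, the two paths
#' @export
exportCountMatrix <- function(counts, condition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "counts.tsv")
  dpath <- file.path(dir, "design.tsv")
  utils::write.table(data.frame(tsn = rownames(counts), counts,
                                check.names = FALSE),
                     cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(counts),
                                condition = condition),
                     dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(cpath, dpath))
}
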