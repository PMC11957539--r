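#' Default pipeline configuration
#'
#' Plain list (losslessly YAML-round-trippable via
#' \code{\link{writeConfig}}/\code{\link{readConfig}}) of paths, thresholds
#' and stage toggles. All randomness flows from the single \code{seed}.
#'
#' @param outdir output directory
#' @return config list
#' @export
defaultConfig <- function(outdir = tempfile("m6amquant")) {
  list(
    outdir = outdir,
    seed = 1L,
    umi_length = 8L,
    simulate = list(enabled = TRUE, n_genes = 10L, n_spikeins = 3L,
                    n_molecules = 4000L, conversion_rate = 1.0,
                    methyl_protection = 0.99, pcr_duplication_rate = 0.2,
                    internal_leakage_rate = 0.02),
    fastq1 = NULL, fastq2 = NULL, reference_fasta = NULL,
    annotation_bed = NULL, external_sam = NULL,
    preprocess = list(enabled = TRUE, min_quality = 20L, min_length = 32L),
    align = list(enabled = TRUE, k = 5L, max_mismatch = 4L,
                 mismatch_penalty = 6L, min_best_score = -10L,
                 min_score_gap = 9L),
    thresholds = list(discovery_min = 20L, quantify_min = 50L),
    annotate = list(max_distance = 100L),
    motifs = list(enabled = TRUE),
    internal_m6a = list(enabled = TRUE, min_reads = 20L, min_rate = 0.1,
                        alpha = 0.05, region_rate_cap = 0.05,
                        min_gene_counts = 1000L))
}

#' Write / read a pipeline config as YAML
#'
#' @param config config list
#' @param path YAML path
#' @return invisibly the path; \code{readConfig} returns the list
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) yaml::read_yaml(path)

.write_metrics <- function(metrics, path) {
  jsonlite::write_json(as.list(metrics), path, auto_unbox = TRUE,
                       digits = NA)
}

#' Run the pipeline end to end
#'
#' Stage order: simulate (optional) -> preprocess -> align -> TSN pileup ->
#' gene annotation -> promoter motifs -> expression -> internal m6A. Each
#' stage writes its table plus a JSON metrics block to the output
#' directory; a rerun with the same config reproduces identical tables.
#' With \code{preprocess$enabled = FALSE} and an \code{external_sam} path
#' the pipeline starts from the provided alignments.
#'
#' @param config list from \code{\link{defaultConfig}} (or a YAML path)
#' @return invisibly, the output directory
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- readConfig(config)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  reference <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sc <- config$simulate
    reference <- makeToyReference(sc$n_genes, sc$n_spikeins, seed = seed)
    params <- LibraryParams(umi_length = config$umi_length,
      conversion_rate = sc$conversion_rate,
      methyl_protection = sc$methyl_protection,
      n_molecules = sc$n_molecules,
      pcr_duplication_rate = sc$pcr_duplication_rate,
      internal_leakage_rate = sc$internal_leakage_rate, seed = seed)
    sim <- simulateLibrary(reference, params = params)
    Biostrings::writeXStringSet(refSeqs(reference),
                                file.path(out, "reference.fasta"))
    writeAnnotationBed(reference, file.path(out, "annotation.bed"))
    writeFastqPair(sim$reads, file.path(out, "reads_R1.fastq"),
                   file.path(out, "reads_R2.fastq"))
    writeTruthTable(sim$truth, file.path(out, "truth.tsv"))
    reads <- sim$reads
    .write_metrics(c(n_reads = nrow(sim$reads),
                     n_unique_molecules =
                       sum(is.na(truthMolecules(sim$truth)$duplicate_of))),
                   file.path(out, "metrics_simulate.json"))
  } else {
    seqs <- Biostrings::readDNAStringSet(config$reference_fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    ann <- readAnnotationBed(config$annotation_bed)
    reference <- new("ToyReference", seqs = seqs, annotation = ann,
                     isoforms = data.frame())
    reads <- if (!is.null(config$fastq1))
      readFastqPair(config$fastq1, config$fastq2) else NULL
  }

  if (isTRUE(config$preprocess$enabled)) {
    pp <- preprocessReads(reads, umi_length = config$umi_length,
                          min_quality = config$preprocess$min_quality,
                          min_length = config$preprocess$min_length)
    stopifnot(nrow(pp$records) + nrow(pp$rejects) == nrow(reads))
    utils::write.table(pp$rejects, file.path(out, "preprocess_rejects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_metrics(pp$metrics, file.path(out, "metrics_preprocess.json"))
    al <- alignReads(pp$records, reference,
                     min_best_score = config$align$min_best_score,
                     min_score_gap = config$align$min_score_gap,
                     k = config$align$k,
                     max_mismatch = config$align$max_mismatch,
                     mismatch_penalty = config$align$mismatch_penalty)
    alignments <- al$alignments
    .write_metrics(al$metrics, file.path(out, "metrics_align.json"))
    writeAlignmentsSAM(alignments, reference,
                       file.path(out, "alignments.sam"))
  } else {
    alignments <- importAlignmentsSAM(config$external_sam)
    alignments <- dedupAlignments(alignments)
    .write_metrics(c(imported = nrow(alignments)),
                   file.path(out, "metrics_align.json"))
  }

  thr <- coverageThresholds(config$thresholds$discovery_min,
                            config$thresholds$quantify_min)
  tsn <- pileupTSN(alignments, reference)
  tsn <- callAndMerge(tsn, thr)
  tsn <- assignGenes(tsn, reference,
                     max_distance = config$annotate$max_distance)
  writeTsnBed(tsn, file.path(out, "tsn.bed"))
  .write_metrics(c(n_sites = length(tsn),
                   n_discovery = sum(tsn$tier != "raw"),
                   n_quantified = sum(tsn$tier == "quantified")),
                 file.path(out, "metrics_tsn.json"))

  gene_summary <- geneComposition(tsn[tsn$tier == "quantified"])
  utils::write.table(gene_summary, file.path(out, "gene_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (isTRUE(config$motifs$enabled)) {
    a_tsn <- tsn[tsn$tsn_base == "A" & tsn$tier == "quantified"]
    if (length(a_tsn)) {
      win <- promoterWindows(a_tsn, reference)
      ok <- windowBases(win$window, 1L)[, 1L] == "A"
      win <- win[ok, , drop = FALSE]
      if (nrow(win)) {
        win$motif <- classifyTSSMotif(win$window)
        win$tata <- findTATA(win$window)
        utils::write.table(win[, c("chrom", "strand", "pos", "motif",
                                   "tata", "non_conversion")],
                           file.path(out, "motifs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
  }

  # per-TSN expression (single-sample TPM on deduplicated molecule counts)
  key <- paste(as.character(GenomicRanges::seqnames(tsn)),
               GenomicRanges::start(tsn),
               as.character(GenomicRanges::strand(tsn)), sep = ":")
  expr <- calcTPM(stats::setNames(tsn$coverage, key))
  utils::write.table(expr, file.path(out, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (isTRUE(config$internal_m6a$enabled)) {
    ali2 <- alignments
    m <- match(paste(ali2$chrom, ali2$strand,
                     ifelse(ali2$strand == "+", ali2$m1_start, ali2$m1_end)),
               paste(as.character(GenomicRanges::seqnames(tsn)),
                     as.character(GenomicRanges::strand(tsn)),
                     GenomicRanges::start(tsn)))
    ali2$gene_id <- tsn$gene_id[m]
    ip <- internalPileup(ali2, reference)
    nf <- readNoiseFilter(ip$long)
    bg <- geneBackground(nf$long,
                         min_counts = config$internal_m6a$min_gene_counts)
    calls <- callInternalM6A(nf$long, bg,
      min_reads = config$internal_m6a$min_reads,
      min_rate = config$internal_m6a$min_rate,
      alpha = config$internal_m6a$alpha,
      region_rate_cap = config$internal_m6a$region_rate_cap)
    utils::write.table(calls, file.path(out, "internal_m6a.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_metrics(c(candidate_sites = nrow(calls),
                     called = sum(calls$called),
                     noisy_read_excluded_fraction = nf$excluded_fraction),
                   file.path(out, "metrics_internal_m6a.json"))
  }
  invisible(out)
}
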