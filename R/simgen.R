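#' Generate a toy reference genome with annotated TSSs and isoforms
#'
#' Builds a deterministic random reference for desk-scale pipeline testing:
#' one contig per gene (plus dedicated contigs for spike-ins), a
#' single-nucleotide TSS annotation per gene, and 1--10 5' isoforms per gene
#' whose start positions lie within 100 nt of the annotated TSS. The
#' annotated TSS base is forced to A on the transcript strand so every gene
#' has at least one A-TSN; additional isoforms start on whatever base the
#' random sequence provides. A-initiated isoforms receive a uniform random
#' m6Am stoichiometry; spike-ins are single-isoform, fully methylated genes
#' on their own contigs.
#'
#' @param n_genes number of genes (>= 1)
#' @param n_spikeins number of spike-in contigs (>= 0)
#' @param seed integer seed; the same seed reproduces the reference exactly
#' @param chrom_length contig length for genes (spike-ins use 400 nt)
#' @param max_isoforms upper bound on isoforms per gene (1--10)
#' @return a \code{\linkS4class{ToyReference}}
#' @examples
#' ref <- makeToyReference(3, n_spikeins = 1, seed = 7)
#' ref
#' @export
makeToyReference <- function(n_genes, n_spikeins = 0L, seed = 1L,
                             chrom_length = 1200L, max_isoforms = 10L) {
  n_genes <- .check_count(n_genes, "n_genes")
  if (length(n_spikeins) != 1L || is.na(n_spikeins) || n_spikeins < 0L)
    stop("'n_spikeins' must be a non-negative count", call. = FALSE)
  n_spikeins <- as.integer(n_spikeins)
  max_isoforms <- max(1L, min(10L, as.integer(max_isoforms)))
  biotypes <- c("protein_coding", "lncRNA", "snRNA", "snoRNA", "other")

  withr::with_seed(as.integer(seed), {
    seqs <- character(0); seq_names <- character(0)
    ann <- list(); iso <- list()
    for (i in seq_len(n_genes)) {
      chrom <- sprintf("chr%d", i)
      s <- paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
                 collapse = "")
      strand <- if (i %% 2L == 1L) "+" else "-"
      tss <- if (strand == "+") 300L else chrom_length - 300L
      # force the annotated TSS base to A on the transcript strand
      base_at_tss <- if (strand == "+") "A" else "T"
      substr(s, tss, tss) <- base_at_tss
      gene_id <- sprintf("gene%03d", i)
      biotype <- sample(biotypes, 1L,
                        prob = c(0.6, 0.15, 0.1, 0.1, 0.05))
      n_iso <- sample.int(max_isoforms, 1L)
      offs <- c(0L, sample(setdiff(-100:100, 0L), n_iso - 1L))
      pos <- tss + offs
      tsn_base <- vapply(pos, function(p) {
        b <- substr(s, p, p)
        if (strand == "+") b else .complement_chr(b)
      }, character(1))
      stoich <- ifelse(tsn_base == "A", stats::runif(n_iso), NA_real_)
      iso[[i]] <- data.frame(gene_id = gene_id, chrom = chrom,
        strand = strand, tsn_position = pos, tsn_base = tsn_base,
        expression_weight = stats::runif(n_iso, 0.5, 1.5),
        m6am_stoichiometry = stoich, stringsAsFactors = FALSE)
      ann[[i]] <- data.frame(chrom = chrom, pos = tss, strand = strand,
        gene_id = gene_id, biotype = biotype, stringsAsFactors = FALSE)
      seqs <- c(seqs, s); seq_names <- c(seq_names, chrom)
    }
    for (j in seq_len(n_spikeins)) {
      chrom <- sprintf("spikein%d", j)
      s <- paste(sample(c("A", "C", "G", "T"), 400L, replace = TRUE),
                 collapse = "")
      tss <- 150L
      substr(s, tss, tss) <- "A"
      gene_id <- sprintf("spike%03d", j)
      iso[[n_genes + j]] <- data.frame(gene_id = gene_id, chrom = chrom,
        strand = "+", tsn_position = tss, tsn_base = "A",
        expression_weight = 1, m6am_stoichiometry = 1,
        stringsAsFactors = FALSE)
      ann[[n_genes + j]] <- data.frame(chrom = chrom, pos = tss,
        strand = "+", gene_id = gene_id, biotype = "spikein",
        stringsAsFactors = FALSE)
      seqs <- c(seqs, s); seq_names <- c(seq_names, chrom)
    }
    ann <- do.call(rbind, ann)
    iso <- do.call(rbind, iso)
    iso$internal_m6a <- replicate(nrow(iso),
      data.frame(offset = integer(0), stoichiometry = numeric(0)),
      simplify = FALSE)
    gr <- GenomicRanges::GRanges(ann$chrom,
      IRanges::IRanges(ann$pos, ann$pos), strand = ann$strand,
      gene_id = ann$gene_id, biotype = ann$biotype)
    new("ToyReference",
        seqs = stats::setNames(Biostrings::DNAStringSet(seqs), seq_names),
        annotation = gr, isoforms = iso)
  })
}

#' Reference for mixed methylation standards
#'
#' Emulates the five-standard benchmarking design: for each target m6Am
#' fraction, a set of barcoded single-isoform transcripts with an A start
#' nucleotide at that stoichiometry. Each transcript gets its own contig so
#' all standards align unambiguously.
#'
#' @param mixes expected m6Am fractions of the standards
#' @param transcripts_per_mix barcoded transcripts per standard
#' @param seed integer seed
#' @return a \code{ToyReference}; gene ids are \code{std<k>_tx<i>} and the
#'   isoform table carries a \code{standard} attribute mapping gene to mix.
#' @export
makeStandardsReference <- function(mixes = c(0, 0.25, 0.5, 0.75, 1),
                                   transcripts_per_mix = 5L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    seqs <- character(0); nm <- character(0)
    ann <- list(); iso <- list(); k <- 0L
    for (m in seq_along(mixes)) {
      for (i in seq_len(transcripts_per_mix)) {
        k <- k + 1L
        chrom <- sprintf("std%d_tx%d", m, i)
        s <- paste(sample(c("A", "C", "G", "T"), 400L, replace = TRUE),
                   collapse = "")
        tss <- 150L
        substr(s, tss, tss) <- "A"
        gene_id <- chrom
        iso[[k]] <- data.frame(gene_id = gene_id, chrom = chrom,
          strand = "+", tsn_position = tss, tsn_base = "A",
          expression_weight = 1, m6am_stoichiometry = mixes[m],
          stringsAsFactors = FALSE)
        ann[[k]] <- data.frame(chrom = chrom, pos = tss, strand = "+",
          gene_id = gene_id, biotype = "other", standard = mixes[m],
          stringsAsFactors = FALSE)
        seqs <- c(seqs, s); nm <- c(nm, chrom)
      }
    }
    ann <- do.call(rbind, ann); iso <- do.call(rbind, iso)
    iso$internal_m6a <- replicate(nrow(iso),
      data.frame(offset = integer(0), stoichiometry = numeric(0)),
      simplify = FALSE)
    gr <- GenomicRanges::GRanges(ann$chrom,
      IRanges::IRanges(ann$pos, ann$pos), strand = ann$strand,
      gene_id = ann$gene_id, biotype = ann$biotype,
      standard = ann$standard)
    new("ToyReference",
        seqs = stats::setNames(Biostrings::DNAStringSet(seqs), nm),
        annotation = gr, isoforms = iso)
  })
}

#' Apply nitrite deamination chemistry to a transcript-strand sequence
#'
#' Sodium nitrite deaminates unmethylated A to inosine, which reverse
#' transcription reads as G; N6-methylated A (m6A/m6Am) resists. The methyl
#' mask marks methylated A positions. With \code{conversion_rate = 1} and
#' \code{methyl_protection = 1} the operation is deterministic: every
#' unmasked A becomes G, every masked A stays A, and C/G/T are untouched.
#'
#' @param sequence nucleotide string (transcript strand)
#' @param methyl_mask logical vector, one per base; TRUE only at A positions
#' @param conversion_rate probability an unmasked A reads as G
#' @param methyl_protection probability a masked A reads as A
#' @param seed optional seed for the stochastic regime
#' @return converted nucleotide string of identical length
#' @examples
#' applyNitriteChemistry("AAGC", c(TRUE, FALSE, FALSE, FALSE))
#' @export
applyNitriteChemistry <- function(sequence, methyl_mask,
                                  conversion_rate = 1,
                                  methyl_protection = 1, seed = NULL) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(methyl_mask) != length(ch))
    stop("mask length must equal sequence length", call. = FALSE)
  if (any(methyl_mask & ch != "A"))
    stop("methyl_mask TRUE at a non-A position", call. = FALSE)
  run <- function() {
    isA <- ch == "A"
    conv <- isA & !methyl_mask & (stats::runif(length(ch)) < conversion_rate)
    lost <- isA & methyl_mask & (stats::runif(length(ch)) >= methyl_protection)
    ch[conv | lost] <- "G"
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Vectorised chemistry over a character matrix of fragments (rows =
# molecules); mask is a logical matrix of methylated positions.
.convert_matrix <- function(chmat, mask, conversion_rate, methyl_protection) {
  isA <- chmat == "A"
  mask <- mask & isA
  u <- matrix(stats::runif(length(chmat)), nrow = nrow(chmat))
  conv <- isA & !mask & (u < conversion_rate)
  u2 <- matrix(stats::runif(length(chmat)), nrow = nrow(chmat))
  lost <- isA & mask & (u2 >= methyl_protection)
  chmat[conv | lost] <- "G"
  chmat
}

.mutate_reads <- function(x, rate) {
  if (rate <= 0) return(x)
  ch <- strsplit(x, "", fixed = TRUE)
  vapply(ch, function(v) {
    hit <- stats::runif(length(v)) < rate
    if (any(hit)) {
      v[hit] <- vapply(v[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    paste(v, collapse = "")
  }, character(1))
}

#' Simulate a nitrite-conversion cap-enriched paired-end library
#'
#' Draws molecules from the isoform table (multinomially, by expression
#' weight), applies nitrite chemistry with per-molecule methylation marks,
#' and emits read pairs with the library adapter structure: read 1 is
#' UMI + "ATAT" + the converted transcript 5' sequence; read 2 is the
#' reverse complement of the fragment 3' end. A configurable fraction of
#' molecules are enrichment-leakage fragments whose 5' ends are uniform
#' internal positions. PCR duplicates share the parent molecule's UMI and
#' coordinates. UMIs are drawn without replacement so duplicate collapse by
#' exact UMI is lossless.
#'
#' @param reference a \code{ToyReference}
#' @param isoforms isoform table (defaults to \code{isoformSpecs(reference)})
#' @param params a \code{\linkS4class{LibraryParams}}
#' @return list with \code{reads} (data.frame: read_id, read1, read2,
#'   qual1, qual2) and \code{truth} (a \code{\linkS4class{TruthTable}})
#' @export
simulateLibrary <- function(reference, isoforms = isoformSpecs(reference),
                            params = LibraryParams()) {
  stopifnot(is(reference, "ToyReference"), is(params, "LibraryParams"))
  validObject(params)
  if (is.null(isoforms) || nrow(isoforms) == 0L)
    stop("empty isoform list", call. = FALSE)
  ann_genes <- tssAnnotation(reference)$gene_id
  if (!all(isoforms$gene_id %in% ann_genes))
    stop("isoform references a gene absent from the annotation",
         call. = FALSE)
  chrom_seqs <- as.character(refSeqs(reference))
  n <- params@n_molecules
  umi_len <- params@umi_length
  frag_len <- params@fragment_length
  rlen <- params@read_length
  r1_insert <- rlen - umi_len - 4L
  if (n > 4^umi_len)
    stop("n_molecules exceeds the UMI space", call. = FALSE)

  withr::with_seed(params@seed, {
    idx <- sample.int(nrow(isoforms), n, replace = TRUE,
                      prob = isoforms$expression_weight)
    chrom <- isoforms$chrom[idx]
    strand <- isoforms$strand[idx]
    tsn <- isoforms$tsn_position[idx]
    clen <- nchar(chrom_seqs)[match(chrom, names(chrom_seqs))]
    avail <- ifelse(strand == "+", clen - tsn + 1L, tsn)
    leak <- stats::runif(n) < params@internal_leakage_rate
    max_off <- pmax(avail - frag_len, 1L)
    off <- ifelse(leak, floor(stats::runif(n) * max_off) + 1L, 0L)
    five_pos <- ifelse(strand == "+", tsn + off, tsn - off)
    tsn_base <- ifelse(leak, NA_character_, isoforms$tsn_base[idx])
    stoich <- isoforms$m6am_stoichiometry[idx]
    meth <- !leak & !is.na(tsn_base) & tsn_base == "A" &
      !is.na(stoich) & (stats::runif(n) < stoich)

    frags <- vapply(seq_len(n), function(i)
      .transcript_seq(chrom_seqs[[chrom[i]]], five_pos[i], strand[i],
                      frag_len), character(1))
    chmat <- matrix(unlist(strsplit(frags, "", fixed = TRUE), use.names = FALSE),
                    nrow = n, byrow = TRUE)
    mask <- matrix(FALSE, nrow = n, ncol = frag_len)
    mask[cbind(which(meth), rep(1L, sum(meth)))] <- TRUE
    # internal m6A marks: offsets are relative to the isoform TSN (+1 = TSN)
    has_int <- vapply(isoforms$internal_m6a, nrow, integer(1)) > 0L
    if (any(has_int[idx])) {
      for (i in which(has_int[idx])) {
        im <- isoforms$internal_m6a[[idx[i]]]
        rel <- im$offset + 1L - off[i]   # column in this molecule's fragment
        keep <- rel >= 1L & rel <= frag_len
        if (any(keep)) {
          on <- stats::runif(sum(keep)) < im$stoichiometry[keep]
          mask[i, rel[keep][on]] <- TRUE
        }
      }
    }
    chmat <- .convert_matrix(chmat, mask, params@conversion_rate,
                             params@methyl_protection)
    conv <- apply(chmat, 1L, paste, collapse = "")

    umis <- .index_to_umi(sample.int(4^umi_len, n, replace = FALSE), umi_len)
    mol_id <- sprintf("mol%06d", seq_len(n))
    ndup <- stats::rgeom(n, 1 - params@pcr_duplication_rate)
    parent <- rep(seq_len(n), ndup + 1L)
    is_dup <- unlist(lapply(ndup + 1L, function(k) c(FALSE, rep(TRUE, k - 1L))),
                     use.names = FALSE)
    copy_n <- unlist(lapply(ndup + 1L, seq_len), use.names = FALSE)

    read1 <- paste0(umis[parent], "ATAT", substr(conv[parent], 1L, r1_insert))
    read2 <- .revcomp_chr(substr(conv[parent], frag_len - rlen + 1L, frag_len))
    if (params@sequencing_error_rate > 0) {
      read1 <- .mutate_reads(read1, params@sequencing_error_rate)
      read2 <- .mutate_reads(read2, params@sequencing_error_rate)
    }
    read_id <- ifelse(is_dup,
                      sprintf("%s.dup%d", mol_id[parent], copy_n - 1L),
                      mol_id[parent])
    qual <- strrep("I", rlen)
    reads <- data.frame(read_id = read_id, read1 = read1, read2 = read2,
                        qual1 = qual, qual2 = qual, stringsAsFactors = FALSE)

    molecules <- data.frame(
      molecule_id = read_id,
      gene_id = isoforms$gene_id[idx][parent],
      chrom = chrom[parent], strand = strand[parent],
      tsn_position = five_pos[parent],
      tsn_base = vapply(parent, function(i) {
        b <- substr(chrom_seqs[[chrom[i]]], five_pos[i], five_pos[i])
        if (strand[i] == "+") b else .complement_chr(b)
      }, character(1)),
      tsn_methylated = meth[parent],
      duplicate_of = ifelse(is_dup, mol_id[parent], NA_character_),
      is_leakage = leak[parent], umi = umis[parent],
      stringsAsFactors = FALSE)

    uniq <- molecules[is.na(molecules$duplicate_of) & !molecules$is_leakage, ]
    key <- paste(uniq$chrom, uniq$strand, uniq$tsn_position)
    agg <- data.table::as.data.table(uniq)
    sites <- as.data.frame(agg[, list(
      tsn_base = tsn_base[1L],
      n_molecules = .N,
      n_methylated = sum(tsn_methylated)),
      by = c("chrom", "strand", "tsn_position")])
    sites$expected_stoichiometry <- ifelse(sites$tsn_base == "A",
      sites$n_methylated / sites$n_molecules, NA_real_)
    truth <- new("TruthTable", molecules = molecules, sites = sites)
    list(reads = reads, truth = truth)
  })
}

#' Write / read a ground-truth table
#'
#' TSV serialisation: one row per molecule record, then a \code{#SITES}
#' sentinel line followed by the per-site summary block. The round trip is
#' lossless.
#'
#' @param truth a \code{TruthTable}
#' @param path output path
#' @return invisibly, the path
#' @export
writeTruthTable <- function(truth, path) {
  stopifnot(is(truth, "TruthTable"))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(truthMolecules(truth), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("#SITES", con)
  utils::write.table(truthSites(truth), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  lines <- readLines(path)
  cut <- match("#SITES", lines)
  mol <- utils::read.table(text = lines[seq_len(cut - 1L)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(duplicate_of = "character"))
  mol$duplicate_of[mol$duplicate_of %in% c("NA", "")] <- NA_character_
  sit <- utils::read.table(text = lines[-seq_len(cut)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  if (nrow(mol) == 0L)
    mol <- truthMolecules(new("TruthTable",
      molecules = .empty_molecules(), sites = .empty_sites()))
  new("TruthTable", molecules = mol, sites = sit)
}

.empty_molecules <- function() data.frame(molecule_id = character(0),
  gene_id = character(0), chrom = character(0), strand = character(0),
  tsn_position = integer(0), tsn_base = character(0),
  tsn_methylated = logical(0), duplicate_of = character(0),
  is_leakage = logical(0), umi = character(0), stringsAsFactors = FALSE)

.empty_sites <- function() data.frame(chrom = character(0),
  strand = character(0), tsn_position = integer(0), tsn_base = character(0),
  n_molecules = integer(0), n_methylated = integer(0),
  expected_stoichiometry = numeric(0), stringsAsFactors = FALSE)
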