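#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
NULL

#' Toy reference genome with TSS annotation
#'
#' A small in-memory reference used throughout the package: chromosome
#' sequences, a point annotation of transcription-start sites (one per gene,
#' with a biotype), and a table of 5' isoform specifications (per-isoform
#' start nucleotide, expression weight, m6Am stoichiometry and any internal
#' m6A marks) used by the library simulator.
#'
#' @slot seqs \code{DNAStringSet} of chromosome sequences (alphabet A/C/G/T).
#' @slot annotation \code{GRanges} of single-nucleotide TSS positions with
#'   metadata columns \code{gene_id} and \code{biotype} (one of
#'   \code{snRNA}, \code{snoRNA}, \code{protein_coding}, \code{lncRNA},
#'   \code{other}, \code{spikein}).
#' @slot isoforms \code{data.frame} with columns \code{gene_id},
#'   \code{chrom}, \code{strand}, \code{tsn_position} (1-based),
#'   \code{tsn_base}, \code{expression_weight}, \code{m6am_stoichiometry},
#'   \code{internal_m6a} (list column of data.frames with \code{offset},
#'   \code{stoichiometry}).
#'
#' @export
setClass("ToyReference",
  representation(seqs = "DNAStringSet", annotation = "GRanges",
                 isoforms = "data.frame"))

setValidity("ToyReference", function(object) {
  msg <- character()
  if (length(object@seqs) == 0L || any(Biostrings::width(object@seqs) == 0L))
    msg <- c(msg, "chromosome sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(object@seqs, baseOnly = TRUE)
  if (length(object@seqs) && any(freq[, "other"] > 0))
    msg <- c(msg, "sequence alphabet must be A/C/G/T only")
  ann <- object@annotation
  if (length(ann)) {
    if (is.null(ann$gene_id) || is.null(ann$biotype))
      msg <- c(msg, "annotation needs gene_id and biotype metadata")
    else if (anyDuplicated(ann$gene_id))
      msg <- c(msg, "gene_ids must be unique")
    lens <- stats::setNames(Biostrings::width(object@seqs),
                            names(object@seqs))
    chr <- as.character(GenomicRanges::seqnames(ann))
    if (!all(chr %in% names(lens)))
      msg <- c(msg, "annotation chromosome absent from sequences")
    else if (any(GenomicRanges::start(ann) < 1L |
                 GenomicRanges::end(ann) > lens[chr]))
      msg <- c(msg, "TSS position outside its chromosome")
  }
  iso <- object@isoforms
  if (nrow(iso)) {
    if (any(iso$expression_weight < 0))
      msg <- c(msg, "expression weights must be >= 0")
    w <- tapply(iso$expression_weight, iso$gene_id, sum)
    if (any(w <= 0))
      msg <- c(msg, "weights over a gene must sum > 0")
    s <- iso$m6am_stoichiometry
    if (any(s < 0 | s > 1, na.rm = TRUE))
      msg <- c(msg, "m6am_stoichiometry must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ToyReference chromosome sequences
#' @param x,object a \code{ToyReference}
#' @export
setGeneric("refSeqs", function(x) standardGeneric("refSeqs"))
#' @export
setMethod("refSeqs", "ToyReference", function(x) x@seqs)

#' @describeIn ToyReference TSS annotation as \code{GRanges}
#' @export
setGeneric("tssAnnotation", function(x) standardGeneric("tssAnnotation"))
#' @export
setMethod("tssAnnotation", "ToyReference", function(x) x@annotation)

#' @describeIn ToyReference isoform specification table
#' @export
setGeneric("isoformSpecs", function(x) standardGeneric("isoformSpecs"))
#' @export
setMethod("isoformSpecs", "ToyReference", function(x) x@isoforms)

setMethod("show", "ToyReference", function(object) {
  cat("ToyReference with", length(object@seqs), "sequences (",
      sum(Biostrings::width(object@seqs)), "bp ),",
      length(object@annotation), "annotated TSSs,",
      nrow(object@isoforms), "isoforms\n")
  bt <- table(object@annotation$biotype)
  cat("  biotypes:", paste(names(bt), bt, sep = ":", collapse = " "), "\n")
})

#' Library simulation parameters
#'
#' Chemistry and library-structure parameters for \code{\link{simulateLibrary}}.
#' Defaults mirror near-ideal nitrite chemistry: complete deamination of
#' unmethylated A (\code{conversion_rate = 1}) and 0.99 protection of
#' methylated A, matching the >95 percent purity of the cap analogs used to
#' build methylated standards.
#'
#' @slot umi_length UMI length, 8 or 11 nt.
#' @slot spacer fixed spacer between UMI and the transcript 5' end ("ATAT").
#' @slot conversion_rate probability an unmethylated A is read as G.
#' @slot methyl_protection probability a methylated A is read as A.
#' @slot read_length total read length (read 1 includes UMI + spacer).
#' @slot fragment_length length of the cap-proximal fragment each molecule
#'   contributes (must exceed \code{read_length}).
#' @slot n_molecules number of unique molecules to draw.
#' @slot pcr_duplication_rate in [0,1); each molecule gains
#'   \code{rgeom(1 - rate)} PCR duplicate reads.
#' @slot internal_leakage_rate fraction of molecules drawn from internal
#'   fragment 5' ends (imperfect cap enrichment).
#' @slot sequencing_error_rate uniform substitution rate per sequenced base.
#' @slot seed integer seed; fixed seed implies byte-identical output.
#' @export
setClass("LibraryParams",
  representation(umi_length = "integer", spacer = "character",
    conversion_rate = "numeric", methyl_protection = "numeric",
    read_length = "integer", fragment_length = "integer",
    n_molecules = "integer", pcr_duplication_rate = "numeric",
    internal_leakage_rate = "numeric", sequencing_error_rate = "numeric",
    seed = "integer"),
  prototype(umi_length = 8L, spacer = "ATAT", conversion_rate = 1.0,
    methyl_protection = 0.99, read_length = 50L, fragment_length = 80L,
    n_molecules = 1000L, pcr_duplication_rate = 0.0,
    internal_leakage_rate = 0.02, sequencing_error_rate = 0.0, seed = 1L))

setValidity("LibraryParams", function(object) {
  msg <- character()
  if (!object@umi_length %in% c(8L, 11L))
    msg <- c(msg, "umi_length must be 8 or 11")
  if (!identical(object@spacer, "ATAT"))
    msg <- c(msg, "spacer must be ATAT")
  for (p in c("conversion_rate", "methyl_protection", "sequencing_error_rate")) {
    v <- slot(object, p)
    if (length(v) != 1L || v < 0 || v > 1)
      msg <- c(msg, paste(p, "must lie in [0,1]"))
  }
  for (p in c("pcr_duplication_rate", "internal_leakage_rate")) {
    v <- slot(object, p)
    if (length(v) != 1L || v < 0 || v >= 1)
      msg <- c(msg, paste(p, "must lie in [0,1)"))
  }
  if (object@n_molecules < 1L) msg <- c(msg, "n_molecules must be >= 1")
  if (object@fragment_length <= object@read_length)
    msg <- c(msg, "fragment_length must exceed read_length")
  if (object@read_length <= object@umi_length + 5L)
    msg <- c(msg, "read_length too short for UMI + spacer + insert")
  if (length(msg)) msg else TRUE
})

#' Construct library simulation parameters
#'
#' @param umi_length,conversion_rate,methyl_protection,read_length
#'   see \code{\linkS4class{LibraryParams}}.
#' @param fragment_length,n_molecules,pcr_duplication_rate see
#'   \code{\linkS4class{LibraryParams}}.
#' @param internal_leakage_rate,sequencing_error_rate,seed see
#'   \code{\linkS4class{LibraryParams}}.
#' @return a validated \code{LibraryParams} object
#' @export
LibraryParams <- function(umi_length = 8L, conversion_rate = 1.0,
    methyl_protection = 0.99, read_length = 50L,
    fragment_length = read_length + 30L, n_molecules = 1000L,
    pcr_duplication_rate = 0.0, internal_leakage_rate = 0.02,
    sequencing_error_rate = 0.0, seed = 1L) {
  new("LibraryParams", umi_length = as.integer(umi_length),
      spacer = "ATAT", conversion_rate = conversion_rate,
      methyl_protection = methyl_protection,
      read_length = as.integer(read_length),
      fragment_length = as.integer(fragment_length),
      n_molecules = as.integer(n_molecules),
      pcr_duplication_rate = pcr_duplication_rate,
      internal_leakage_rate = internal_leakage_rate,
      sequencing_error_rate = sequencing_error_rate, seed = as.integer(seed))
}

setMethod("show", "LibraryParams", function(object) {
  cat("LibraryParams:", object@n_molecules, "molecules, UMI",
      object@umi_length, "nt, conversion", object@conversion_rate,
      ", protection", object@methyl_protection, ", dup",
      object@pcr_duplication_rate, ", leakage",
      object@internal_leakage_rate, ", seed", object@seed, "\n")
})

#' Simulation ground truth
#'
#' Per-molecule records and per-site expected stoichiometry emitted by
#' \code{\link{simulateLibrary}}. A site's expected stoichiometry is the
#' fraction of its A-start, non-leakage molecules that carry the N6 methyl.
#'
#' @slot molecules \code{data.frame}: \code{molecule_id}, \code{gene_id},
#'   \code{chrom}, \code{strand}, \code{tsn_position}, \code{tsn_base},
#'   \code{tsn_methylated}, \code{duplicate_of} (NA for originals),
#'   \code{is_leakage}, \code{umi}.
#' @slot sites \code{data.frame}: \code{chrom}, \code{strand},
#'   \code{tsn_position}, \code{tsn_base}, \code{n_molecules} (unique,
#'   non-leakage), \code{n_methylated}, \code{expected_stoichiometry}.
#' @export
setClass("TruthTable",
  representation(molecules = "data.frame", sites = "data.frame"))

setValidity("TruthTable", function(object) {
  m <- object@molecules; s <- object@sites
  need_m <- c("molecule_id", "gene_id", "chrom", "strand", "tsn_position",
              "tsn_base", "tsn_methylated", "duplicate_of", "is_leakage", "umi")
  need_s <- c("chrom", "strand", "tsn_position", "tsn_base", "n_molecules",
              "n_methylated", "expected_stoichiometry")
  msg <- character()
  if (!all(need_m %in% names(m))) msg <- c(msg, "molecule columns incomplete")
  if (!all(need_s %in% names(s))) msg <- c(msg, "site columns incomplete")
  if (length(msg)) msg else TRUE
})

#' @describeIn TruthTable molecule-level records
#' @param x a \code{TruthTable}
#' @export
setGeneric("truthMolecules", function(x) standardGeneric("truthMolecules"))
#' @export
setMethod("truthMolecules", "TruthTable", function(x) x@molecules)

#' @describeIn TruthTable per-site expected stoichiometry
#' @export
setGeneric("truthSites", function(x) standardGeneric("truthSites"))
#' @export
setMethod("truthSites", "TruthTable", function(x) x@sites)

setMethod("show", "TruthTable", function(object) {
  m <- object@molecules
  cat("TruthTable:", nrow(m), "molecule records (",
      sum(is.na(m$duplicate_of)), "unique,", sum(m$is_leakage), "leakage ),",
      nrow(object@sites), "sites\n")
})

#' Strand-specific converted reference
#'
#' Holds the A-to-G converted genome (plus strand) and the T-to-C converted
#' genome (minus strand) together with the original sequences, which act as
#' the provenance map: restoring any converted position means looking up the
#' original base.
#'
#' @slot original,plus,minus \code{DNAStringSet}s of equal widths.
#' @export
setClass("ConvertedReference",
  representation(original = "DNAStringSet", plus = "DNAStringSet",
                 minus = "DNAStringSet"))

setValidity("ConvertedReference", function(object) {
  msg <- character()
  w <- Biostrings::width(object@original)
  if (!identical(w, Biostrings::width(object@plus)) ||
      !identical(w, Biostrings::width(object@minus)))
    msg <- c(msg, "converted sequences must match original widths")
  if (length(object@plus) &&
      sum(Biostrings::vcountPattern("A", object@plus)) > 0)
    msg <- c(msg, "plus-strand reference must contain no A")
  if (length(object@minus) &&
      sum(Biostrings::vcountPattern("T", object@minus)) > 0)
    msg <- c(msg, "minus-strand reference must contain no T")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConvertedReference", function(object) {
  cat("ConvertedReference over", length(object@original), "sequences,",
      sum(Biostrings::width(object@original)), "bp\n")
})
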