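#' Build strand-specific converted references
#'
#' Three-base alignment space: the plus-strand reference has every A
#' replaced by G (matching A-to-G converted read 1), the minus-strand
#' reference every T replaced by C (matching T-to-C converted read 2 and
#' minus-strand transcripts). The original sequences are retained as the
#' provenance map; restoring any position is a lookup into them.
#'
#' @param reference a \code{\linkS4class{ToyReference}} or
#'   \code{DNAStringSet}
#' @return a \code{\linkS4class{ConvertedReference}}
#' @examples
#' cr <- buildConvertedReference(Biostrings::DNAStringSet(c(chr = "ACGT")))
#' @export
buildConvertedReference <- function(reference) {
  seqs <- if (is(reference, "ToyReference")) refSeqs(reference)
          else Biostrings::DNAStringSet(reference)
  orig <- as.character(seqs)
  plus <- Biostrings::DNAStringSet(chartr("A", "G", orig))
  minus <- Biostrings::DNAStringSet(chartr("T", "C", orig))
  names(plus) <- names(minus) <- names(seqs)
  new("ConvertedReference", original = seqs, plus = plus, minus = minus)
}

#' Restore the original genome from a converted reference
#'
#' Inversion identity used by tests: the provenance map reproduces the
#' original sequences exactly.
#'
#' @param convref a \code{ConvertedReference}
#' @return \code{DNAStringSet} equal to the pre-conversion genome
#' @export
restoreReference <- function(convref) convref@original

#' In silico conversion of a read pair
#'
#' Read 1 is A-to-G converted and read 2 T-to-C converted so both mates can
#' be placed in the three-base alignment space; the original sequences are
#' retained in \code{mate1_orig}/\code{mate2_orig} for base restoration
#' after alignment. The operation is idempotent on its own output.
#'
#' @param records accepted records (from \code{\link{preprocessReads}})
#' @return records with \code{mate1}/\code{mate2} converted and originals
#'   kept in \code{mate1_orig}/\code{mate2_orig}
#' @export
convertReadPair <- function(records) {
  out <- records
  if (is.null(out$mate1_orig)) out$mate1_orig <- records$mate1
  if (is.null(out$mate2_orig)) out$mate2_orig <- records$mate2
  out$mate1 <- chartr("A", "G", records$mate1)
  out$mate2 <- chartr("T", "C", records$mate2)
  out
}

# Hits of `pattern` in a DNAStringSet at <= mm mismatches: data.frame of
# (chrom, start, end, nm).
.hits_in_set <- function(pattern, subject_set, mm) {
  m <- Biostrings::vmatchPattern(pattern, subject_set, max.mismatch = mm)
  res <- list()
  pat <- Biostrings::DNAString(pattern)
  for (i in seq_along(m)) {
    ir <- m[[i]]
    if (length(ir) == 0L) next
    st <- BiocGenerics::start(ir)
    keep <- st >= 1L & BiocGenerics::end(ir) <=
      Biostrings::width(subject_set)[i]
    st <- st[keep]
    if (length(st) == 0L) next
    nm <- vapply(st, function(s)
      Biostrings::neditAt(pat, subject_set[[i]], at = s), integer(1))
    res[[length(res) + 1L]] <- data.frame(
      chrom = names(subject_set)[i], start = st,
      end = st + nchar(pattern) - 1L, nm = nm, stringsAsFactors = FALSE)
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(chrom = character(0), start = integer(0),
                  end = integer(0), nm = integer(0))
}

#' Find candidate placements for converted read pairs
#'
#' End-to-end, ungapped placement of both mates in conversion space, on both
#' strand-specific references, scored on the aligner convention where a
#' perfect pair scores 0 and each mismatch costs \code{mismatch_penalty}
#' (pair score = mate 1 + mate 2). Up to \code{k} highest-scoring candidates
#' are returned per pair. Mates must be in FR orientation on the same
#' contig within \code{max_insert}. Identical read-pair sequences are
#' aligned once and fanned back out, which makes near-duplicate-free
#' converted libraries fast to place.
#'
#' @param records converted records from \code{\link{convertReadPair}}
#' @param convref a \code{ConvertedReference}
#' @param k maximum candidates per pair (default 5)
#' @param max_mismatch per-mate mismatch cap for the search (default 4)
#' @param mismatch_penalty score cost per mismatch (default 6)
#' @param max_insert maximum outer fragment span (default 600)
#' @return data.frame of candidates: \code{read_id}, \code{umi},
#'   \code{chrom}, \code{strand}, mate coordinates, mismatch counts,
#'   \code{score}, \code{clip5}
#' @export
alignCandidates <- function(records, convref, k = 5L, max_mismatch = 4L,
                            mismatch_penalty = 6L, max_insert = 600L) {
  stopifnot(is(convref, "ConvertedReference"))
  if (nrow(records) == 0L) return(.empty_candidates())
  if (any(grepl("[^ACGTN]", records$mate1)) ||
      any(grepl("[^ACGTN]", records$mate2)))
    stop("read alphabet must be A/C/G/T/N", call. = FALSE)
  key <- paste(records$mate1, records$mate2, sep = "|")
  uniq <- !duplicated(key)
  ukey <- key[uniq]
  um1 <- records$mate1[uniq]
  um2 <- records$mate2[uniq]

  per_pair <- vector("list", length(ukey))
  for (j in seq_along(ukey)) {
    m1c <- um1[j]; m2c <- um2[j]
    cand <- list()
    # plus strand: mate1 forward, mate2 reverse-complemented, both in plus ref
    h1 <- .hits_in_set(m1c, convref@plus, max_mismatch)
    if (nrow(h1)) {
      h2 <- .hits_in_set(.revcomp_chr(m2c), convref@plus, max_mismatch)
      if (nrow(h2)) {
        mg <- merge(h1, h2, by = "chrom", suffixes = c("1", "2"))
        if (nrow(mg)) {
          ok <- mg$start2 >= mg$start1 & mg$end2 >= mg$end1 &
            (mg$end2 - mg$start1 + 1L) <= max_insert
          mg <- mg[ok, , drop = FALSE]
          if (nrow(mg))
            cand[[length(cand) + 1L]] <- data.frame(
              chrom = mg$chrom, strand = "+",
              m1_start = mg$start1, m1_end = mg$end1,
              m2_start = mg$start2, m2_end = mg$end2,
              nm1 = mg$nm1, nm2 = mg$nm2, stringsAsFactors = FALSE)
        }
      }
    }
    # minus strand: mate1 reverse-complemented, mate2 forward, in minus ref
    h1m <- .hits_in_set(.revcomp_chr(m1c), convref@minus, max_mismatch)
    if (nrow(h1m)) {
      h2m <- .hits_in_set(m2c, convref@minus, max_mismatch)
      if (nrow(h2m)) {
        mg <- merge(h1m, h2m, by = "chrom", suffixes = c("1", "2"))
        if (nrow(mg)) {
          ok <- mg$start2 <= mg$start1 & mg$end2 <= mg$end1 &
            (mg$end1 - mg$start2 + 1L) <= max_insert
          mg <- mg[ok, , drop = FALSE]
          if (nrow(mg))
            cand[[length(cand) + 1L]] <- data.frame(
              chrom = mg$chrom, strand = "-",
              m1_start = mg$start1, m1_end = mg$end1,
              m2_start = mg$start2, m2_end = mg$end2,
              nm1 = mg$nm1, nm2 = mg$nm2, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(cand)) {
      cc <- do.call(rbind, cand)
      cc$score <- -mismatch_penalty * (cc$nm1 + cc$nm2)
      cc <- cc[order(-cc$score, cc$chrom, cc$m1_start), , drop = FALSE]
      per_pair[[j]] <- utils::head(cc, k)
    }
  }
  names(per_pair) <- ukey
  out <- list()
  for (i in seq_len(nrow(records))) {
    cc <- per_pair[[key[i]]]
    if (is.null(cc) || nrow(cc) == 0L) next
    cc$read_id <- records$read_id[i]
    cc$umi <- if (!is.null(records$umi)) records$umi[i] else NA_character_
    out[[length(out) + 1L]] <- cc
  }
  if (!length(out)) return(.empty_candidates())
  res <- do.call(rbind, out)
  res$clip5 <- 0L
  rownames(res) <- NULL
  res[, c("read_id", "umi", "chrom", "strand", "m1_start", "m1_end",
          "m2_start", "m2_end", "nm1", "nm2", "score", "clip5")]
}

.empty_candidates <- function() data.frame(read_id = character(0),
  umi = character(0), chrom = character(0), strand = character(0),
  m1_start = integer(0), m1_end = integer(0), m2_start = integer(0),
  m2_end = integer(0), nm1 = integer(0), nm2 = integer(0),
  score = integer(0), clip5 = integer(0), stringsAsFactors = FALSE)

#' Disambiguate candidate placements by score and score gap
#'
#' A pair is kept only when its best placement is trustworthy: the best
#' pair score must be higher than \code{min_best_score} (-10) and, when a
#' secondary placement exists, the best must beat it by more than
#' \code{min_score_gap} (9). Equal-scoring co-optimal placements (including
#' the same locus hit on both strand references) therefore yield no
#' assignment.
#'
#' @param candidates candidate table from \code{\link{alignCandidates}}
#' @param min_best_score best score must exceed this (default -10)
#' @param min_score_gap best minus second must exceed this (default 9)
#' @return data.frame with one row per uniquely assigned read pair
#' @export
disambiguate <- function(candidates, min_best_score = -10L,
                         min_score_gap = 9L) {
  if (min_score_gap < 0L) stop("min_score_gap must be >= 0", call. = FALSE)
  if (nrow(candidates) == 0L) return(candidates)
  dt <- data.table::as.data.table(candidates)
  data.table::setorder(dt, read_id, -score)
  pick <- dt[, {
    if (score[1L] > min_best_score &&
        (.N == 1L || score[1L] - score[2L] > min_score_gap)) .SD[1L]
    else .SD[0L]
  }, by = "read_id"]
  as.data.frame(pick)
}

#' Restore original bases and drop 5'-softclipped alignments
#'
#' Replaces the conversion-space sequences of uniquely placed pairs with
#' the original base calls (so A-vs-G status at every reference position is
#' recoverable) and rejects any alignment whose mate 1 has a softclip at
#' its 5' end, where the transcription-start nucleotide must be anchored.
#' 3'-only clips are acceptable.
#'
#' @param best one-row-per-read table from \code{\link{disambiguate}}
#' @param records the (converted) records the candidates were built from;
#'   must carry \code{mate1_orig}/\code{mate2_orig}
#' @return list with \code{alignments} (restored) and \code{rejects}
#' @export
restoreAndFilter <- function(best, records) {
  if (nrow(best) == 0L)
    return(list(alignments = cbind(best,
                  data.frame(mate1 = character(0), mate2 = character(0))),
                rejects = data.frame(read_id = character(0),
                                     reason = character(0))))
  m <- match(best$read_id, records$read_id)
  if (anyNA(m))
    stop("candidate read absent from records", call. = FALSE)
  orig1 <- records$mate1_orig[m]
  orig2 <- records$mate2_orig[m]
  span <- best$m1_end - best$m1_start + 1L
  if (any(nchar(orig1) != span))
    stop("restoration length mismatch between read and alignment",
         call. = FALSE)
  keep <- best$clip5 == 0L
  out <- best[keep, , drop = FALSE]
  out$mate1 <- orig1[keep]
  out$mate2 <- orig2[keep]
  rownames(out) <- NULL
  list(alignments = out,
       rejects = data.frame(read_id = best$read_id[!keep],
                            reason = rep("softclip-5p", sum(!keep)),
                            stringsAsFactors = FALSE))
}

#' Collapse PCR duplicates by exact UMI
#'
#' One representative is kept per (chrom, strand, mate 1 5' coordinate,
#' exact UMI) key -- the unique-UMI method. The representative is the
#' alignment with the highest pair score, ties broken by lexicographically
#' smallest read id. UMIs differing by a single base are distinct molecules.
#'
#' @param alignments restored alignments from \code{\link{restoreAndFilter}}
#' @return deduplicated alignment table
#' @export
dedupAlignments <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  if (is.null(alignments$umi) || anyNA(alignments$umi))
    stop("alignments must carry a UMI", call. = FALSE)
  dt <- data.table::as.data.table(alignments)
  dt[, five_prime := ifelse(strand == "+", m1_start, m1_end)]
  data.table::setorder(dt, chrom, strand, five_prime, umi, -score, read_id)
  out <- dt[, .SD[1L], by = c("chrom", "strand", "five_prime", "umi")]
  cols <- c(names(alignments), "five_prime")
  as.data.frame(out)[, cols]
}

#' Write restored alignments as SAM
#'
#' Minimal coordinate-sorted text SAM of mate 1 with restored SEQ; the UMI
#' travels in the \code{RX} tag and the pair score in \code{AS}. Minus-strand
#' records are reverse-complemented per SAM convention.
#'
#' @param alignments restored (optionally deduplicated) alignments
#' @param reference the \code{ToyReference} the alignments refer to
#' @param path output path
#' @return invisibly, the path
#' @export
writeAlignmentsSAM <- function(alignments, reference, path) {
  seqs <- refSeqs(reference)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), Biostrings::width(seqs)))
  a <- alignments[order(alignments$chrom, alignments$m1_start), , drop = FALSE]
  flag <- ifelse(a$strand == "-", 16L, 0L)
  seq_out <- ifelse(a$strand == "-", .revcomp_chr(a$mate1), a$mate1)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tAS:i:%d\tRX:Z:%s",
                   a$read_id, flag, a$chrom, a$m1_start,
                   a$m1_end - a$m1_start + 1L, seq_out, a$score, a$umi)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# cigar helpers for the external-SAM path
.cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (m[1L] == -1L) return(data.frame(len = integer(0), op = character(0)))
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

#' Import externally produced alignments from a SAM file
#'
#' Supports the external-aligner route: a text SAM whose records carry the
#' original (restored) sequence in SEQ, the alignment score in \code{AS},
#' and the UMI either in an \code{RX} tag or as the \code{_UMI} suffix of
#' the read name. The 5'-softclip length is derived from the CIGAR relative
#' to the read's 5' end (leading clip for plus strand, trailing for minus).
#'
#' @param path SAM path
#' @return alignment table compatible with \code{\link{dedupAlignments}}
#' @export
importAlignmentsSAM <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(.empty_candidates())
  f <- strsplit(lines, "\t", fixed = TRUE)
  get_tag <- function(v, tag) {
    hit <- grep(paste0("^", tag, ":"), v[-(1:11)], value = TRUE)
    if (length(hit)) sub("^[A-Za-z0-9]+:[AifZ]:", "", hit[1L]) else NA_character_
  }
  res <- lapply(f, function(v) {
    flag <- as.integer(v[2L])
    strand <- if (bitwAnd(flag, 16L)) "-" else "+"
    cig <- .cigar_ops(v[6L])
    ref_len <- sum(cig$len[cig$op %in% c("M", "D", "N", "=", "X")])
    clip_lead <- if (nrow(cig) && cig$op[1L] == "S") cig$len[1L] else 0L
    clip_trail <- if (nrow(cig) && cig$op[nrow(cig)] == "S")
      cig$len[nrow(cig)] else 0L
    clip5 <- if (strand == "+") clip_lead else clip_trail
    seq <- if (strand == "-") .revcomp_chr(v[10L]) else v[10L]
    as_tag <- get_tag(v, "AS")
    rx <- get_tag(v, "RX")
    umi <- if (!is.na(rx)) rx else sub("^.*_", "", v[1L])
    data.frame(read_id = v[1L], umi = umi, chrom = v[3L], strand = strand,
      m1_start = as.integer(v[4L]),
      m1_end = as.integer(v[4L]) + ref_len - 1L,
      m2_start = NA_integer_, m2_end = NA_integer_,
      nm1 = NA_integer_, nm2 = NA_integer_,
      score = if (is.na(as_tag)) 0L else as.integer(as_tag),
      clip5 = clip5, mate1 = seq, mate2 = NA_character_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Align preprocessed records end to end
#'
#' Convenience wrapper: in silico conversion, candidate search,
#' disambiguation, restoration/5'-clip filtering, and UMI deduplication.
#'
#' @param records accepted records from \code{\link{preprocessReads}}
#' @param reference a \code{ToyReference} or \code{ConvertedReference}
#' @param ... passed to \code{\link{alignCandidates}} and
#'   \code{\link{disambiguate}}
#' @param min_best_score,min_score_gap see \code{\link{disambiguate}}
#' @return list with \code{alignments} (deduplicated), \code{metrics}
#' @export
alignReads <- function(records, reference, min_best_score = -10L,
                       min_score_gap = 9L, ...) {
  convref <- if (is(reference, "ConvertedReference")) reference
             else buildConvertedReference(reference)
  conv <- convertReadPair(records)
  cand <- alignCandidates(conv, convref, ...)
  best <- disambiguate(cand, min_best_score, min_score_gap)
  rf <- restoreAndFilter(best, conv)
  ded <- dedupAlignments(rf$alignments)
  list(alignments = ded,
       metrics = c(input = nrow(records),
                   with_candidates = length(unique(cand$read_id)),
                   unique_placement = nrow(best),
                   softclip5_rejected = nrow(rf$rejects),
                   deduped = nrow(ded)))
}
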