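#' Extract the UMI and ATAT spacer from read 1
#'
#' The library adapter places an 8 or 11 nt UMI followed by a fixed ATAT
#' spacer at the start of read 1; the base immediately after the spacer is
#' the transcription-start nucleotide. Pairs whose spacer does not match
#' exactly are rejected ("bad-spacer"); pairs too short to contain
#' UMI + spacer + at least one transcript base are rejected ("too-short").
#' The UMI is appended to the read id after an underscore, and UMI + spacer
#' are removed from mate 1. Mate 2 is never altered.
#'
#' @param reads data.frame with \code{read_id}, \code{read1}, \code{read2},
#'   \code{qual1}, \code{qual2} (e.g. from \code{\link{readFastqPair}} or
#'   \code{\link{simulateLibrary}})
#' @param umi_length 8 or 11
#' @return list with \code{records} (accepted reads: \code{read_id},
#'   \code{umi}, \code{mate1}, \code{mate2}, \code{qual1}, \code{qual2}) and
#'   \code{rejects} (read_id, reason)
#' @export
extractUMI <- function(reads, umi_length = 8L) {
  if (!umi_length %in% c(8L, 11L))
    stop("umi_length must be 8 or 11", call. = FALSE)
  umi_length <- as.integer(umi_length)
  min_len <- umi_length + 5L
  too_short <- nchar(reads$read1) < min_len
  spacer <- substr(reads$read1, umi_length + 1L, umi_length + 4L)
  bad <- !too_short & spacer != "ATAT"
  ok <- !too_short & !bad
  ids <- if (any(ok)) paste0(reads$read_id[ok], "_",
                             substr(reads$read1[ok], 1L, umi_length))
         else character(0)
  records <- data.frame(
    read_id = ids,
    umi = substr(reads$read1[ok], 1L, umi_length),
    mate1 = substr(reads$read1[ok], umi_length + 5L, nchar(reads$read1[ok])),
    mate2 = reads$read2[ok],
    qual1 = substr(reads$qual1[ok], umi_length + 5L, nchar(reads$qual1[ok])),
    qual2 = reads$qual2[ok], stringsAsFactors = FALSE)
  rejects <- data.frame(
    read_id = reads$read_id[!ok],
    reason = ifelse(too_short[!ok], "too-short", "bad-spacer"),
    stringsAsFactors = FALSE)
  list(records = records, rejects = rejects)
}

# Cutadapt-style 3' quality trimming: subtract the threshold from each
# quality, cumulate from the 3' end, cut where the partial sum is minimal.
.qtrim_len <- function(qual, threshold) {
  q <- as.integer(charToRaw(qual)) - 33L
  s <- rev(cumsum(rev(q - threshold)))
  cuts <- which(s < 0)
  if (length(cuts) == 0L) nchar(qual) else min(cuts) - 1L
}

#' Quality- and length-trim accepted records
#'
#' 3' end quality trimming at the given Phred threshold (cutadapt partial-sum
#' algorithm) on both mates; records whose mate 1 falls below
#' \code{min_length} after trimming are rejected. Trimming is idempotent.
#'
#' @param records accepted records from \code{\link{extractUMI}}
#' @param min_quality Phred threshold (default 20)
#' @param min_length minimum post-trim mate 1 length (default 32)
#' @return list with \code{records} and \code{rejects} (reason "too-short")
#' @export
qualityTrim <- function(records, min_quality = 20L, min_length = 32L) {
  if (nrow(records) == 0L)
    return(list(records = records,
                rejects = data.frame(read_id = character(0),
                                     reason = character(0))))
  l1 <- vapply(records$qual1, .qtrim_len, integer(1), min_quality,
               USE.NAMES = FALSE)
  l2 <- vapply(records$qual2, .qtrim_len, integer(1), min_quality,
               USE.NAMES = FALSE)
  out <- records
  out$mate1 <- substr(out$mate1, 1L, l1)
  out$qual1 <- substr(out$qual1, 1L, l1)
  out$mate2 <- substr(out$mate2, 1L, l2)
  out$qual2 <- substr(out$qual2, 1L, l2)
  keep <- nchar(out$mate1) >= min_length
  list(records = out[keep, , drop = FALSE],
       rejects = data.frame(read_id = records$read_id[!keep],
                            reason = rep("too-short", sum(!keep)),
                            stringsAsFactors = FALSE))
}

#' Trim adapter read-through from mate 2
#'
#' When the fragment is shorter than the read, mate 2 runs into the reverse
#' complement of the 5' adapter: \code{ATAT} + UMI + sequencing adapter.
#' The suffix is located by scanning for the earliest position where
#' \code{ATAT} is followed by \code{umi_length} arbitrary bases and the
#' fixed adapter, allowing up to 1 mismatch per 10 fixed bases compared.
#'
#' @param records records from \code{\link{extractUMI}}
#' @param umi_length 8 or 11
#' @param adapter fixed sequencing adapter after the UMI
#' @return records with mate 2 (and its qualities) truncated at the adapter
#' @export
trimMate2Adapter <- function(records, umi_length = 8L,
                             adapter = "AGATCGGAAGAGCGTCGTG") {
  if (nrow(records) == 0L) return(records)
  pat_fixed <- c("ATAT", adapter)
  find_cut <- function(seq) {
    n <- nchar(seq)
    for (start in seq_len(n)) {
      # fixed part 1: ATAT at `start`
      mism <- 0L; compared <- 0L; pos <- start
      segs <- list(c("ATAT", 0L), c(adapter, 4L + umi_length))
      ok <- TRUE
      for (sg in segs) {
        s0 <- start + as.integer(sg[2L])
        piece <- substr(seq, s0, min(n, s0 + nchar(sg[1L]) - 1L))
        if (nchar(piece) == 0L) break
        ref <- substr(sg[1L], 1L, nchar(piece))
        d <- sum(strsplit(piece, "")[[1]] != strsplit(ref, "")[[1]])
        mism <- mism + d; compared <- compared + nchar(piece)
        if (s0 + nchar(sg[1L]) - 1L > n) break
      }
      if (compared >= 4L && mism <= max(1L, compared %/% 10L))
        return(start - 1L)
    }
    n
  }
  cuts <- vapply(records$mate2, find_cut, integer(1), USE.NAMES = FALSE)
  records$mate2 <- substr(records$mate2, 1L, cuts)
  records$qual2 <- substr(records$qual2, 1L, cuts)
  records
}

#' Run the full preprocessing stage
#'
#' UMI/spacer extraction, optional mate 2 adapter trimming, then quality and
#' length trimming. Accepted plus rejected record counts always equal the
#' input count.
#'
#' @param reads raw read table (see \code{\link{extractUMI}})
#' @param umi_length 8 or 11
#' @param min_quality,min_length see \code{\link{qualityTrim}}
#' @param trim_mate2 logical; scan mate 2 for adapter read-through
#' @return list with \code{records}, \code{rejects}, and \code{metrics}
#'   (named counts)
#' @export
preprocessReads <- function(reads, umi_length = 8L, min_quality = 20L,
                            min_length = 32L, trim_mate2 = FALSE) {
  ex <- extractUMI(reads, umi_length)
  rec <- ex$records
  if (trim_mate2) rec <- trimMate2Adapter(rec, umi_length)
  qt <- qualityTrim(rec, min_quality, min_length)
  rejects <- rbind(ex$rejects, qt$rejects)
  metrics <- c(input = nrow(reads), accepted = nrow(qt$records),
               rejected = nrow(rejects))
  list(records = qt$records, rejects = rejects, metrics = metrics)
}
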