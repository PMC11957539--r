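#' Extract core-promoter windows around TSNs
#'
#' Returns the transcript-strand sequence from offset -40 to +41 relative to
#' each TSN (position +1 is the TSN itself; there is no offset 0), 81 nt in
#' total. Windows running off a contig are dropped.
#'
#' @param tsn \code{GRanges} of TSN records
#' @param reference a \code{ToyReference} (or \code{DNAStringSet})
#' @param up,down offsets covered upstream/downstream (defaults -40/+41)
#' @return data.frame: \code{chrom}, \code{strand}, \code{pos},
#'   \code{window} (81 nt string), plus carried-over \code{non_conversion}
#'   when present
#' @export
promoterWindows <- function(tsn, reference, up = 40L, down = 41L) {
  seqs <- if (is(reference, "ToyReference")) as.character(refSeqs(reference))
          else as.character(Biostrings::DNAStringSet(reference))
  chrom <- as.character(GenomicRanges::seqnames(tsn))
  strand <- as.character(GenomicRanges::strand(tsn))
  pos <- GenomicRanges::start(tsn)
  lens <- nchar(seqs)[chrom]
  lo <- ifelse(strand == "+", pos - up, pos - (down - 1L))
  hi <- ifelse(strand == "+", pos + (down - 1L), pos + up)
  ok <- lo >= 1L & hi <= lens
  win <- character(sum(ok))
  idx <- which(ok)
  for (j in seq_along(idx)) {
    i <- idx[j]
    s <- substr(seqs[[chrom[i]]], lo[i], hi[i])
    win[j] <- if (strand[i] == "+") s else .revcomp_chr(s)
  }
  out <- data.frame(chrom = chrom[ok], strand = strand[ok], pos = pos[ok],
                    window = win, stringsAsFactors = FALSE)
  if (!is.null(tsn$non_conversion)) out$non_conversion <- tsn$non_conversion[ok]
  attr(out, "up") <- as.integer(up)
  out
}

# Signed promoter offset -> string index inside a window whose first base is
# offset -up; +1 is the TSN, there is no offset 0.
.offset_index <- function(offset, up = 40L) {
  stopifnot(all(offset != 0L))
  ifelse(offset < 0L, offset + up + 1L, offset + up)
}

#' Fetch window bases at signed promoter offsets
#'
#' @param window promoter window string(s) (first base = offset \code{-up})
#' @param offsets signed offsets (no 0; +1 = TSN)
#' @param up upstream extent of the window (default 40)
#' @return character matrix, rows = windows, columns = offsets
#' @export
windowBases <- function(window, offsets, up = 40L) {
  idx <- .offset_index(as.integer(offsets), up)
  out <- vapply(idx, function(i) substr(window, i, i), character(length(window)))
  if (length(window) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- as.character(offsets)
  out
}

# Default TSS motif patterns: named list of (offset -> IUPAC code),
# evaluated in priority order.
TSS_MOTIFS <- list(
  SSCA_GC = c(`-3` = "S", `-2` = "S", `-1` = "C", `1` = "A", `2` = "G",
              `3` = "C"),
  BBCA_BW = c(`-3` = "B", `-2` = "B", `-1` = "C", `1` = "A", `2` = "B",
              `3` = "W"),
  VA_RR   = c(`-1` = "V", `1` = "A", `2` = "R", `3` = "R"),
  BA      = c(`-1` = "B", `1` = "A"))

.match_anchored <- function(bases_by_offset, pattern) {
  for (off in names(pattern)) {
    b <- bases_by_offset[[off]]
    if (is.na(b) || !(b %in% IUPAC_SETS[[pattern[[off]]]])) return(FALSE)
  }
  TRUE
}

#' Classify the initiator motif of an A-TSN core promoter
#'
#' Evaluates membership of the -3..+3 context in the four anchored IUPAC
#' initiator patterns (SSCA_+1_GC, BBCA_+1_BW, VA_+1_RR, BA_+1; S = C/G,
#' B = C/G/T, W = A/T, V = A/C/G, R = A/G) and resolves multiple matches by
#' priority SSCA_GC > BBCA_BW > VA_RR > BA (most specific first);
#' non-matching A-TSNs are "other". The window's +1 base must be A.
#'
#' @param window promoter window string(s) (81 nt, first base = offset -40)
#' @param up upstream extent (default 40)
#' @param patterns anchored pattern list; defaults to the four TSS motifs
#' @return character vector of motif labels
#' @examples
#' w <- paste0(strrep("T", 37), "CCC", "AGC", strrep("T", 38))
#' classifyTSSMotif(w)  # SSCA_GC
#' @export
classifyTSSMotif <- function(window, up = 40L, patterns = TSS_MOTIFS) {
  offs <- sort(unique(as.integer(unlist(lapply(patterns, names)))))
  mat <- windowBases(window, offs, up)
  plus1 <- windowBases(window, 1L, up)[, 1L]
  if (any(plus1 != "A"))
    stop("window +1 base must be A for initiator classification",
         call. = FALSE)
  vapply(seq_along(window), function(i) {
    ctx <- as.list(mat[i, , drop = TRUE])
    names(ctx) <- as.character(offs)
    for (lab in names(patterns)) {
      if (.match_anchored(ctx, patterns[[lab]])) return(lab)
    }
    "other"
  }, character(1))
}

#' Detect a TATA box upstream of the TSN
#'
#' TRUE iff the 8-mer TATAWAWR (W = A/T, R = A/G) occurs with its first base
#' at any offset in [-36, -26], i.e. the whole 8-mer lies inside the
#' extended search region -36..-19.
#'
#' @param window promoter window string(s) (first base = offset -40)
#' @param up upstream extent (default 40)
#' @param region_start,region_end search region bounds (defaults -36, -19)
#' @return logical vector
#' @export
findTATA <- function(window, up = 40L, region_start = -36L,
                     region_end = -19L) {
  pat <- c("T", "A", "T", "A", "W", "A", "W", "R")
  starts <- seq(region_start, region_end - 7L)
  starts <- starts[starts < 0L & (starts + 7L) < 0L]
  vapply(window, function(w) {
    for (s0 in starts) {
      idx <- .offset_index(s0 + 0:7, up)
      b <- substring(w, idx, idx)
      ok <- all(mapply(function(bb, pp) bb %in% IUPAC_SETS[[pp]], b, pat))
      if (ok) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' Base frequencies across stoichiometry bins
#'
#' Ranks quantified A-TSNs by non-conversion, splits them into
#' \code{n_bins} equal-count bins (ties broken by coordinate for
#' determinism), and tabulates per-bin base frequencies at every promoter
#' offset in [-40, +41]. Frequencies sum to 1 per bin and offset.
#'
#' @param windows output of \code{\link{promoterWindows}} with a
#'   \code{non_conversion} column
#' @param n_bins number of quantile bins (default 20)
#' @param up upstream extent (default 40)
#' @return 3-d array [bin, offset, base] of frequencies
#' @export
baseFreqByBins <- function(windows, n_bins = 20L, up = 40L) {
  if (any(is.na(windows$non_conversion)))
    stop("non_conversion must be defined for all records", call. = FALSE)
  n <- nrow(windows)
  if (n < n_bins) stop("fewer records than bins", call. = FALSE)
  ord <- order(windows$non_conversion, windows$chrom, windows$pos)
  # equal-count split: assign by rank position
  bin <- integer(n)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  offsets <- c(seq(-up, -1L), seq(1L, 81L - up))
  bases <- c("A", "C", "G", "T")
  out <- array(0, dim = c(n_bins, length(offsets), 4L),
               dimnames = list(paste0("bin", seq_len(n_bins)),
                               as.character(offsets), bases))
  chmat <- matrix(unlist(strsplit(windows$window, "", fixed = TRUE),
                         use.names = FALSE), nrow = n, byrow = TRUE)
  for (b in seq_len(n_bins)) {
    sub <- chmat[bin == b, , drop = FALSE]
    for (k in seq_along(bases))
      out[b, , k] <- colMeans(sub == bases[k])
  }
  out
}

#' Compare stoichiometry between promoter groups
#'
#' Pairwise two-sided Welch t-tests on the per-site stoichiometries of
#' groups defined by motif class or TATA status, with per-group summary
#' statistics. Degenerate groups (n < 2 or zero variance) are flagged and
#' excluded from testing.
#'
#' @param values numeric stoichiometries
#' @param groups group labels, same length
#' @return list with \code{summary} (per group: n, mean, median, IQR,
#'   degenerate flag) and \code{tests} (per pair: t, df, p_value)
#' @export
compareGroups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  labs <- unique(groups)
  if (length(labs) < 2L) stop("need >= 2 groups", call. = FALSE)
  summ <- do.call(rbind, lapply(labs, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               median = stats::median(v), iqr = stats::IQR(v),
               degenerate = length(v) < 2L || stats::var(v) == 0,
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(labs, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    v1 <- values[groups == g1]; v2 <- values[groups == g2]
    deg <- length(v1) < 2L || length(v2) < 2L ||
      (stats::var(v1) == 0 && stats::var(v2) == 0)
    if (deg) {
      ident <- length(v1) == length(v2) && all(sort(v1) == sort(v2))
      data.frame(group1 = g1, group2 = g2,
                 t = if (ident) 0 else NA_real_, df = NA_real_,
                 p_value = if (ident) 1 else NA_real_,
                 degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(v1, v2, var.equal = FALSE,
                          alternative = "two.sided")
      data.frame(group1 = g1, group2 = g2, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  }))
  list(summary = summ, tests = tests)
}

#' Read an anchored IUPAC pattern table
#'
#' Plain-text pattern config: tab-separated lines \code{label<TAB>offset:code}
#' pairs, e.g. \code{BREu -38:S -37:S -36:R -35:C -34:G -33:C -32:C}. Used to
#' extend the motif classifier with user-supplied elements.
#'
#' @param path config path
#' @return named list of anchored patterns usable by
#'   \code{\link{classifyTSSMotif}}
#' @export
readPatternConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    lab <- parts[1L]
    kv <- strsplit(parts[-1L], ":", fixed = TRUE)
    pat <- stats::setNames(vapply(kv, `[`, "", 2L),
                           vapply(kv, `[`, "", 1L))
    out[[lab]] <- pat
  }
  out
}
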