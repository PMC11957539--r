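# Shared fixtures and independent oracles, built in code at test time.

# Minimal hand-built reference: two contigs, one gene each, opposite strands.
tiny_reference <- function(seed = 42L, chrom_length = 800L) {
  makeToyReference(2L, n_spikeins = 0L, seed = seed,
                   chrom_length = chrom_length)
}

# Run simulate -> preprocess -> align for a reference, returning alignments
# plus the truth table.
sim_and_align <- function(reference, params) {
  sim <- simulateLibrary(reference, params = params)
  pp <- preprocessReads(sim$reads, umi_length = params@umi_length)
  al <- alignReads(pp$records, reference)
  list(sim = sim, records = pp$records, alignments = al$alignments,
       metrics = al$metrics)
}

# Independent brute-force oracle for ungapped placement: scans every start
# position of every contig on both converted strands and returns all pair
# placements with per-mate mismatches <= mm, scored like the aligner.
brute_force_candidates <- function(m1c, m2c, convref, mm = 4L,
                                   penalty = 6L, max_insert = 600L) {
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  scan <- function(pattern, subject) {
    pp <- strsplit(pattern, "")[[1]]
    ss <- strsplit(subject, "")[[1]]
    L <- length(pp); n <- length(ss)
    if (n < L) return(data.frame(start = integer(0), nm = integer(0)))
    npos <- n - L + 1L
    mism <- integer(npos)
    for (j in seq_len(L))
      mism <- mism + (ss[seq_len(npos) + j - 1L] != pp[j])
    keep <- which(mism <= mm)
    data.frame(start = keep, nm = mism[keep])
  }
  out <- list()
  for (chrom in names(convref@plus)) {
    plus <- as.character(convref@plus[[chrom]])
    minus <- as.character(convref@minus[[chrom]])
    h1 <- scan(m1c, plus); h2 <- scan(rc(m2c), plus)
    for (i in seq_len(nrow(h1))) for (j in seq_len(nrow(h2))) {
      s1 <- h1$start[i]; s2 <- h2$start[j]
      e1 <- s1 + nchar(m1c) - 1L; e2 <- s2 + nchar(m2c) - 1L
      if (s2 >= s1 && e2 >= e1 && (e2 - s1 + 1L) <= max_insert)
        out[[length(out) + 1L]] <- data.frame(chrom = chrom, strand = "+",
          m1_start = s1, m1_end = e1,
          score = -penalty * (h1$nm[i] + h2$nm[j]))
    }
    h1m <- scan(rc(m1c), minus); h2m <- scan(m2c, minus)
    for (i in seq_len(nrow(h1m))) for (j in seq_len(nrow(h2m))) {
      s1 <- h1m$start[i]; s2 <- h2m$start[j]
      e1 <- s1 + nchar(m1c) - 1L; e2 <- s2 + nchar(m2c) - 1L
      if (s2 <= s1 && e2 <= e1 && (e1 - s2 + 1L) <= max_insert)
        out[[length(out) + 1L]] <- data.frame(chrom = chrom, strand = "-",
          m1_start = s1, m1_end = e1,
          score = -penalty * (h1m$nm[i] + h2m$nm[j]))
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0),
    strand = character(0), m1_start = integer(0), m1_end = integer(0),
    score = integer(0)))
  do.call(rbind, out)
}

# Naive IUPAC membership check used as the motif-classifier oracle.
naive_iupac_match <- function(base, code) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
    Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"), K = c("G", "T"),
    M = c("A", "C"), B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  base %in% sets[[code]]
}

# Oracle classifier over a -3..+3 context written independently of the
# package's matcher (plain nested conditionals on the published patterns).
oracle_classify <- function(b_m3, b_m2, b_m1, b_p1, b_p2, b_p3) {
  stopifnot(b_p1 == "A")
  if (naive_iupac_match(b_m3, "S") && naive_iupac_match(b_m2, "S") &&
      b_m1 == "C" && b_p2 == "G" && b_p3 == "C") return("SSCA_GC")
  if (naive_iupac_match(b_m3, "B") && naive_iupac_match(b_m2, "B") &&
      b_m1 == "C" && naive_iupac_match(b_p2, "B") &&
      naive_iupac_match(b_p3, "W")) return("BBCA_BW")
  if (naive_iupac_match(b_m1, "V") && naive_iupac_match(b_p2, "R") &&
      naive_iupac_match(b_p3, "R")) return("VA_RR")
  if (naive_iupac_match(b_m1, "B")) return("BA")
  "other"
}

# Build an 81-nt promoter window with given bases at signed offsets
# (+1 = position 41); background fill is C.
window_with <- function(..., fill = "C") {
  spec <- list(...)
  w <- rep(fill, 81L)
  for (off in names(spec)) {
    o <- as.integer(off)
    idx <- if (o < 0L) o + 41L else o + 40L
    w[idx] <- spec[[off]]
  }
  paste(w, collapse = "")
}

# Exact binomial upper tail by direct log-space summation (independent of
# pbinom).
tail_by_summation <- function(a, n, p) {
  if (a > n) return(0)
  if (a <= 0) return(1)
  k <- a:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}
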