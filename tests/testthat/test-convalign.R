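test_that("converted references follow the per-base rules and invert", {
  cr <- buildConvertedReference(Biostrings::DNAStringSet(c(x = "ACGT")))
  expect_identical(as.character(cr@plus[["x"]]), "GCGT")
  expect_identical(as.character(cr@minus[["x"]]), "ACGC")
  cc <- buildConvertedReference(Biostrings::DNAStringSet(c(x = "CCCC")))
  expect_identical(as.character(cc@plus[["x"]]), "CCCC")
  expect_identical(as.character(cc@minus[["x"]]), "CCCC")
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
             collapse = "")
  cr2 <- buildConvertedReference(Biostrings::DNAStringSet(c(chr = s)))
  expect_identical(as.character(restoreReference(cr2)[["chr"]]), s)
  expect_identical(sum(Biostrings::vcountPattern("A", cr2@plus)), 0L)
  expect_identical(sum(Biostrings::vcountPattern("T", cr2@minus)), 0L)
})

test_that("read-pair conversion is per-mate and idempotent", {
  rec <- data.frame(read_id = "r", mate1 = "AATAT", mate2 = "AATAT",
                    stringsAsFactors = FALSE)
  conv <- convertReadPair(rec)
  expect_identical(conv$mate1, "GGTGT")
  expect_identical(conv$mate2, "AACAC")
  expect_identical(conv$mate1_orig, "AATAT")
  again <- convertReadPair(conv)
  expect_identical(again$mate1, conv$mate1)
  expect_identical(again$mate2, conv$mate2)
  expect_identical(again$mate1_orig, "AATAT")
})

# a toy genome plus a perfectly matching converted pair placed at `pos`
perfect_pair <- function(genome, pos, m1_len = 20L, frag_len = 40L) {
  frag <- substr(genome, pos, pos + frag_len - 1L)
  data.frame(read_id = "p", umi = "AAAACCCC",
             mate1 = chartr("A", "G", substr(frag, 1L, m1_len)),
             mate2 = chartr("T", "C", as.character(
               Biostrings::reverseComplement(Biostrings::DNAString(
                 substr(frag, frag_len - m1_len + 1L, frag_len))))),
             mate1_orig = substr(frag, 1L, m1_len),
             mate2_orig = "N", stringsAsFactors = FALSE)
}

test_that("a uniquely matching converted pair yields one perfect candidate", {
  set.seed(2)
  g <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  cr <- buildConvertedReference(Biostrings::DNAStringSet(c(chr = g)))
  cand <- alignCandidates(perfect_pair(g, 100L), cr)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$score, 0L)
  expect_identical(cand$m1_start, 100L)
  expect_identical(cand$strand, "+")
})

test_that("two identical loci give two equal-scoring candidates", {
  set.seed(3)
  core <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  pad <- function(n) paste(sample(c("C", "G"), n, replace = TRUE),
                           collapse = "")
  g <- paste0(pad(50), core, pad(80), core, pad(50))
  cr <- buildConvertedReference(Biostrings::DNAStringSet(c(chr = g)))
  pair <- perfect_pair(g, 51L, m1_len = 20L, frag_len = 60L)
  cand <- alignCandidates(pair, cr)
  plus <- cand[cand$strand == "+", ]
  expect_gte(nrow(plus), 2L)
  expect_identical(length(unique(plus$score[1:2])), 1L)
  # and disambiguation refuses the tie
  expect_identical(nrow(disambiguate(cand)), 0L)
})

test_that("candidate search agrees with the brute-force oracle", {
  ref <- makeToyReference(4, seed = 21, chrom_length = 1500L)
  sim <- simulateLibrary(ref, params = LibraryParams(n_molecules = 60L,
                                                     seed = 22L))
  pp <- preprocessReads(sim$reads)
  conv <- convertReadPair(pp$records)
  cr <- buildConvertedReference(ref)
  cand <- alignCandidates(conv, cr, k = 5L)
  for (i in seq_len(nrow(conv))) {
    got <- cand[cand$read_id == conv$read_id[i],
                c("chrom", "strand", "m1_start", "m1_end", "score")]
    oracle <- brute_force_candidates(conv$mate1[i], conv$mate2[i], cr)
    oracle <- oracle[order(-oracle$score, oracle$chrom, oracle$m1_start), ]
    top <- utils::head(oracle, 5L)
    rownames(got) <- rownames(top) <- NULL
    expect_equal(got$score, top$score)
    expect_setequal(paste(got$chrom, got$strand, got$m1_start),
                    paste(top$chrom, top$strand, top$m1_start))
  }
})

test_that("disambiguation applies the -10 score and 9 gap thresholds", {
  mk <- function(scores) data.frame(read_id = "r", umi = "U",
    chrom = "c", strand = "+", m1_start = seq_along(scores),
    m1_end = seq_along(scores) + 9L, m2_start = 1L, m2_end = 10L,
    nm1 = 0L, nm2 = 0L, score = as.integer(scores), clip5 = 0L,
    stringsAsFactors = FALSE)
  expect_identical(disambiguate(mk(c(-5, -20)))$score, -5L)
  expect_identical(nrow(disambiguate(mk(-12))), 0L)           # <= -10
  expect_identical(nrow(disambiguate(mk(c(-5, -10)))), 0L)    # gap 5 <= 9
  expect_identical(nrow(disambiguate(mk(c(-10)))), 0L)        # boundary
  expect_identical(disambiguate(mk(c(-9)))$score, -9L)
  expect_identical(nrow(disambiguate(mk(c(0, -9)))), 0L)      # gap 9, not > 9
  expect_identical(disambiguate(mk(c(0, -10)))$score, 0L)     # gap 10
  expect_error(disambiguate(mk(0), min_score_gap = -1L), ">= 0")
})

test_that("restoration inverts conversion and rejects 5' softclips", {
  set.seed(4)
  g <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  cr <- buildConvertedReference(Biostrings::DNAStringSet(c(chr = g)))
  pair <- perfect_pair(g, 50L)
  cand <- alignCandidates(pair, cr)
  best <- disambiguate(cand)
  rf <- restoreAndFilter(best, pair)
  expect_identical(rf$alignments$mate1, substr(g, 50L, 69L))
  # a 5' softclip on mate1 is rejected; 3'-only clips pass
  best5 <- best; best5$clip5 <- 2L
  rf5 <- restoreAndFilter(best5, pair)
  expect_identical(nrow(rf5$alignments), 0L)
  expect_identical(rf5$rejects$reason, "softclip-5p")
  # restoration length mismatch is an internal-consistency error
  bad <- best; bad$m1_end <- bad$m1_end + 1L
  expect_error(restoreAndFilter(bad, pair), "length mismatch")
})

test_that("dedup keeps one molecule per position+UMI key", {
  base <- data.frame(read_id = c("b", "a"), umi = "AAAA", chrom = "c",
    strand = "+", m1_start = 10L, m1_end = 29L, m2_start = 15L,
    m2_end = 34L, nm1 = 0L, nm2 = 0L, score = c(0L, 0L), clip5 = 0L,
    mate1 = "X", mate2 = "Y", stringsAsFactors = FALSE)
  out <- dedupAlignments(base)
  expect_identical(nrow(out), 1L)
  expect_identical(out$read_id, "a")  # tie broken by smallest read_id
  base$umi <- c("AAAA", "AAAT")       # 1-mismatch UMIs stay distinct
  expect_identical(nrow(dedupAlignments(base)), 2L)
  base$umi <- NA_character_
  expect_error(dedupAlignments(base), "UMI")
})

test_that("dedup recovers the truth unique-molecule count at 50% duplication", {
  ref <- tiny_reference(seed = 31L)
  res <- sim_and_align(ref, LibraryParams(n_molecules = 400L,
    pcr_duplication_rate = 0.5, internal_leakage_rate = 0, seed = 32L))
  truth_unique <- sum(is.na(truthMolecules(res$sim$truth)$duplicate_of))
  expect_identical(nrow(res$alignments), truth_unique)
})

test_that("simulated error-free molecules align to their true TSNs", {
  ref <- makeToyReference(4, seed = 41, chrom_length = 1500L)
  res <- sim_and_align(ref, LibraryParams(n_molecules = 800L, seed = 42L))
  mol <- truthMolecules(res$sim$truth)
  mol <- mol[is.na(mol$duplicate_of), ]
  ali <- res$alignments
  ali$mol <- sub("_.*$", "", ali$read_id)
  m <- match(ali$mol, mol$molecule_id)
  tsn_obs <- ifelse(ali$strand == "+", ali$m1_start, ali$m1_end)
  correct <- ali$chrom == mol$chrom[m] & ali$strand == mol$strand[m] &
    tsn_obs == mol$tsn_position[m]
  expect_gte(mean(correct), 0.99)
  # leakage molecules align, but to internal positions
  expect_true(all(correct[!mol$is_leakage[m]]))
})

test_that("SAM round trip preserves restored alignments", {
  ref <- tiny_reference(seed = 51L)
  res <- sim_and_align(ref, LibraryParams(n_molecules = 60L, seed = 52L))
  path <- tempfile(fileext = ".sam")
  writeAlignmentsSAM(res$alignments, ref, path)
  back <- importAlignmentsSAM(path)
  ord1 <- order(res$alignments$read_id)
  ord2 <- order(back$read_id)
  expect_identical(back$chrom[ord2], res$alignments$chrom[ord1])
  expect_identical(back$m1_start[ord2], res$alignments$m1_start[ord1])
  expect_identical(back$strand[ord2], res$alignments$strand[ord1])
  expect_identical(back$mate1[ord2], res$alignments$mate1[ord1])
  expect_identical(back$umi[ord2], res$alignments$umi[ord1])
})
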