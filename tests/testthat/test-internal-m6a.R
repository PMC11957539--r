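# reference with a run of A's so read bodies contain many reference-A sites
body_ref <- function() {
  s <- paste0(strrep("C", 10), "A",      # TSN at 11
              "CC", "A", "CC", "A", "CCCC", "A", strrep("C", 60))
  ref_from_string(s)
}

ref_from_string <- function(s, name = "chr") {
  new("ToyReference",
      seqs = setNames(Biostrings::DNAStringSet(s), name),
      annotation = GenomicRanges::GRanges(), isoforms = data.frame())
}

body_align <- function(read_bases, n = 1L, start_id = 1L) {
  data.frame(read_id = sprintf("r%03d", start_id:(start_id + n - 1L)),
    umi = sprintf("U%03d", start_id:(start_id + n - 1L)), chrom = "chr",
    strand = "+", m1_start = 11L, m1_end = 10L + nchar(read_bases),
    m2_start = NA_integer_, m2_end = NA_integer_, nm1 = 0L, nm2 = 0L,
    score = 0L, clip5 = 0L, mate1 = read_bases, mate2 = NA_character_,
    gene_id = "g1", stringsAsFactors = FALSE)
}

test_that("the internal pileup excludes the TSN and tracks read bases", {
  ref <- body_ref()
  # reference body from 11: A CC A CC A CCCC A ...
  ali <- body_align("ACCGCCACCCCA", 1L)   # positions 14 read G (converted)
  ip <- internalPileup(ali, ref)
  expect_true(all(ip$long$pos != 11L))    # TSN excluded
  expect_setequal(ip$long$pos, c(14L, 17L, 22L))
  expect_identical(ip$long$read_base[ip$long$pos == 14L], "G")
  expect_identical(ip$long$read_base[ip$long$pos == 17L], "A")
})

test_that("reads with more than three non-converted As are discarded", {
  ref <- ref_from_string(paste0(strrep("C", 10), "A",
                                strrep("AC", 10), strrep("C", 40)))
  # body reference-A offsets: 2,4,6,... read keeps k of them as A
  mk_read <- function(k) {
    b <- rep("G", 20)
    if (k > 0) b[seq(1, by = 2, length.out = 10)[seq_len(k)] ] <- "A"
    # odd body positions are the reference A's (offsets 2,4,... of read)
    paste0("A", paste(ifelse(seq_len(20) %% 2 == 1,
                             b[(seq_len(20) + 1) %/% 2], "C"),
                      collapse = ""))
  }
  ali <- rbind(body_align(mk_read(4), start_id = 1L),
               body_align(mk_read(3), start_id = 2L),
               body_align(mk_read(0), start_id = 3L))
  ip <- internalPileup(ali, ref)
  nf <- readNoiseFilter(ip$long)
  expect_identical(nf$discarded_reads, "r001")   # 4 non-converted
  expect_true(all(c("r002", "r003") %in% nf$long$read_id))
  expect_equal(nf$excluded_fraction, 1 / 3)
})

test_that("gene backgrounds require 1000 counts and pool A/(A+G)", {
  long <- data.frame(read_id = sprintf("r%04d", 1:2000),
    gene_id = rep(c("big", "small"), c(1500, 500)),
    chrom = "chr", strand = "+", pos = 50L,
    read_base = c(rep(c("A", "G"), c(15, 1485)), rep("G", 500)),
    stringsAsFactors = FALSE)
  bg <- geneBackground(long)
  big <- bg[bg$gene_id == "big", ]
  expect_equal(big$background, 15 / 1500)
  expect_false(big$low_gene_coverage)
  small <- bg[bg$gene_id == "small", ]
  expect_true(small$low_gene_coverage)
  expect_true(is.na(small$background))
  # 999 counts: skipped
  long999 <- long[1:999, ]; long999$gene_id <- "edge"
  expect_true(geneBackground(long999)$low_gene_coverage)
  long1000 <- long[1:1000, ]; long1000$gene_id <- "edge"
  expect_false(geneBackground(long1000)$low_gene_coverage)
})

test_that("the binomial tail matches independent exact summation", {
  cases <- data.frame(a = c(1, 10, 3, 50, 200), g = c(9, 20, 27, 9950, 9800),
                      p = c(0.01, 0.01, 0.1, 0.01, 0.02))
  for (i in seq_len(nrow(cases))) {
    a <- cases$a[i]; g <- cases$g[i]; p <- cases$p[i]
    expect_equal(binomialTail(a, g, p), tail_by_summation(a, a + g, p),
                 tolerance = 1e-12)
  }
  expect_equal(binomialTail(0, 10, 0.01), 1)
  # a=10, g=20 vs background 0.01: tail far below 1e-6
  expect_lt(binomialTail(10, 20, 0.01), 1e-6)
})

test_that("the calling cascade applies every filter with its boundary", {
  mk_long <- function(a, g, gene = "g1", pos = 50L, id0 = 1L) {
    data.frame(read_id = sprintf("%s_r%04d", gene, id0:(id0 + a + g - 1L)),
      gene_id = gene, chrom = "chr", strand = "+", pos = pos,
      read_base = rep(c("A", "G"), c(a, g)), stringsAsFactors = FALSE)
  }
  bg <- data.frame(gene_id = "g1", counts = 2000L, background = 0.01,
                   low_gene_coverage = FALSE)
  # a=10 g=20: rate 1/3 > 0.1, p < 1e-6 -> called
  calls <- callInternalM6A(mk_long(10, 20), bg)
  expect_true(calls$called)
  # rate exactly 0.1 is rejected: the rate must exceed 0.1
  calls2 <- callInternalM6A(mk_long(3, 27), bg)
  expect_false(calls2$called)
  expect_identical(calls2$reason, "low_rate")
  # a=0: rate 0 -> low_rate
  calls3 <- callInternalM6A(mk_long(0, 30), bg)
  expect_identical(calls3$reason, "low_rate")
  # coverage below 20 -> low_coverage
  calls4 <- callInternalM6A(mk_long(5, 10), bg)
  expect_identical(calls4$reason, "low_coverage")
  # no background -> low_gene_coverage
  bg_na <- data.frame(gene_id = "g1", counts = 10L, background = NA_real_,
                      low_gene_coverage = TRUE)
  expect_identical(callInternalM6A(mk_long(10, 20), bg_na)$reason,
                   "low_gene_coverage")
})

test_that("conversion-resistant regions are flagged by neighbouring sites", {
  # 30 reads covering two A positions: the focal site is non-converted in
  # half the reads, and the OTHER position is also highly non-converted ->
  # region flag
  n <- 30L
  long <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(read_id = sprintf("r%03d", i), gene_id = "g1",
      chrom = "chr", strand = "+", pos = c(50L, 60L),
      read_base = c(ifelse(i <= 15, "A", "G"), ifelse(i <= 15, "A", "G")),
      stringsAsFactors = FALSE)
  }))
  bg <- data.frame(gene_id = "g1", counts = 2000L, background = 0.01,
                   low_gene_coverage = FALSE)
  calls <- callInternalM6A(long, bg)
  expect_true(all(calls$conversion_resistant_region))
  expect_true(all(calls$reason == "conversion_resistant_region"))
  # clean neighbourhood: the same focal signal with converted neighbours
  long2 <- long
  long2$read_base[long2$pos == 60L] <- "G"
  calls2 <- callInternalM6A(long2, bg)
  focal <- calls2[calls2$pos == 50L, ]
  expect_false(focal$conversion_resistant_region)
  expect_true(focal$called)
})

test_that("planted internal m6A is recovered with high sensitivity", {
  # simulate molecules from one isoform carrying two internal m6A sites at
  # stoichiometry 0.6 and 0.25, with conversion_rate 0.99 providing a
  # nonzero background
  ref <- makeToyReference(1, seed = 101L, chrom_length = 1500L)
  iso <- isoformSpecs(ref)
  iso <- iso[iso$tsn_base == "A", ][1, , drop = FALSE]
  iso$expression_weight <- 1
  iso$m6am_stoichiometry <- 0.9
  seqs <- as.character(refSeqs(ref))
  # find reference-A offsets inside the mate1 insert (38 nt)
  frag <- substr(seqs[[iso$chrom]], iso$tsn_position,
                 iso$tsn_position + 37L)
  if (iso$strand == "-")
    frag <- paste(rev(strsplit(chartr("ACGT", "TGCA",
      substr(seqs[[iso$chrom]], iso$tsn_position - 37L,
             iso$tsn_position)), "")[[1]]), collapse = "")
  a_offs <- which(strsplit(frag, "")[[1]] == "A") - 1L
  a_offs <- a_offs[a_offs >= 5L]
  planted <- a_offs[1:2]
  iso$internal_m6a <- list(data.frame(offset = planted,
                                      stoichiometry = c(0.6, 0.25)))
  sim <- simulateLibrary(ref, iso, LibraryParams(n_molecules = 1500L,
    conversion_rate = 0.99, internal_leakage_rate = 0, seed = 102L))
  pp <- preprocessReads(sim$reads)
  al <- alignReads(pp$records, ref)
  ali <- al$alignments
  ali$gene_id <- iso$gene_id
  ip <- internalPileup(ali, ref)
  nf <- readNoiseFilter(ip$long)
  bg <- geneBackground(nf$long)
  calls <- callInternalM6A(nf$long, bg, region_rate_cap = 0.2)
  g_strand_pos <- if (iso$strand == "+") iso$tsn_position + planted
                  else iso$tsn_position - planted
  planted_rows <- calls[calls$pos %in% g_strand_pos, ]
  expect_identical(nrow(planted_rows), 2L)
  expect_true(all(planted_rows$called))
  expect_equal(planted_rows$non_conversion[order(planted_rows$pos %in%
    g_strand_pos[1], decreasing = TRUE)][1], 0.6, tolerance = 0.15)
  # false calls on unplanted reference-A positions are rare
  unplanted <- calls[!calls$pos %in% g_strand_pos, ]
  expect_lte(mean(unplanted$called), 0.01)
})
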