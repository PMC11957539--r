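test_that("promoter windows are 81 nt with the TSN at +1", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  substr(s, 150, 150) <- "A"
  ref <- Biostrings::DNAStringSet(c(chr = s))
  tsn <- GenomicRanges::GRanges("chr", IRanges::IRanges(150, 150),
                                strand = "+")
  win <- promoterWindows(tsn, ref)
  expect_identical(nchar(win$window), 81L)
  expect_identical(unname(windowBases(win$window, 1L)[, 1L]), "A")
  expect_identical(unname(windowBases(win$window, -1L)[, 1L]),
                   substr(s, 149, 149))
  expect_identical(unname(windowBases(win$window, 41L)[, 1L]),
                   substr(s, 190, 190))
  # minus strand: window is the reverse complement
  substr(s, 150, 150) <- "T"
  ref2 <- Biostrings::DNAStringSet(c(chr = s))
  tsn2 <- GenomicRanges::GRanges("chr", IRanges::IRanges(150, 150),
                                 strand = "-")
  win2 <- promoterWindows(tsn2, ref2)
  expect_identical(unname(windowBases(win2$window, 1L)[, 1L]), "A")
  expect_identical(unname(windowBases(win2$window, -1L)[, 1L]),
                   chartr("ACGT", "TGCA", substr(s, 151, 151)))
  # windows running off the contig are dropped
  edge <- GenomicRanges::GRanges("chr", IRanges::IRanges(10, 10),
                                 strand = "+")
  expect_identical(nrow(promoterWindows(edge, ref)), 0L)
})

test_that("initiator motifs classify per the anchored IUPAC patterns", {
  w1 <- window_with(`-3` = "C", `-2` = "C", `-1` = "C", `1` = "A",
                    `2` = "G", `3` = "C")
  expect_identical(classifyTSSMotif(w1), "SSCA_GC")
  w2 <- window_with(`-1` = "A", `1` = "A", `2` = "A", `3` = "G",
                    `-3` = "A", `-2` = "A")
  expect_identical(classifyTSSMotif(w2), "VA_RR")
  # T,T,C,A,G,C: BBCA_BW fails on +3 (C not in W); VA_RR fails on +3
  # (C not in R); -1 C is in B -> BA
  w3 <- window_with(`-3` = "T", `-2` = "T", `-1` = "C", `1` = "A",
                    `2` = "G", `3` = "C", `-40` = "A")
  expect_identical(classifyTSSMotif(w3), "BA")
  expect_error(classifyTSSMotif(window_with(`1` = "G")), "must be A")
})

test_that("classifier agrees with the brute-force matcher on all 4^6 contexts", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(m3 = bases, m2 = bases, m1 = bases,
                      p2 = bases, p3 = bases, p4 = bases,
                      stringsAsFactors = FALSE)
  wins <- vapply(seq_len(nrow(grid)), function(i)
    window_with(`-3` = grid$m3[i], `-2` = grid$m2[i], `-1` = grid$m1[i],
                `1` = "A", `2` = grid$p2[i], `3` = grid$p3[i],
                `4` = grid$p4[i]), character(1))
  got <- classifyTSSMotif(wins)
  want <- vapply(seq_len(nrow(grid)), function(i)
    oracle_classify(grid$m3[i], grid$m2[i], grid$m1[i], "A",
                    grid$p2[i], grid$p3[i]), character(1))
  expect_identical(got, want)
  expect_true(all(c("SSCA_GC", "BBCA_BW", "VA_RR", "BA", "other") %in% got))
})

test_that("TATA detection respects the -36..-19 region", {
  # TATAWAWR starting at -31: the classic placement
  tata <- c("T", "A", "T", "A", "A", "A", "A", "G")
  w <- do.call(window_with, setNames(as.list(tata),
                                     as.character(-31:-24)))
  expect_true(findTATA(w))
  # same 8-mer starting at -36 (latest-allowed start is -26)
  w36 <- do.call(window_with, setNames(as.list(tata),
                                       as.character(-36:-29)))
  expect_true(findTATA(w36))
  w26 <- do.call(window_with, setNames(as.list(tata),
                                       as.character(-26:-19)))
  expect_true(findTATA(w26))
  # starting at -25 the 8-mer would end at -18, outside the region
  w25 <- do.call(window_with, setNames(as.list(tata),
                                       as.character(-25:-18)))
  expect_false(findTATA(w25))
  # near the TSN (-10) it does not count
  w10 <- do.call(window_with, setNames(as.list(tata),
                                       as.character(c(-10:-3))))
  expect_false(findTATA(w10))
  expect_false(findTATA(strrep("C", 81)))
  # shift consistency: moving the 8-mer by one inside the region keeps TRUE
  for (s0 in -36:-26) {
    ws <- do.call(window_with, setNames(as.list(tata),
                                        as.character(s0 + 0:7)))
    expect_true(findTATA(ws))
  }
})

test_that("stoichiometry bins give equal counts and ordered frequencies", {
  set.seed(6)
  n <- 40L
  nc <- runif(n)
  wins <- data.frame(chrom = "c", strand = "+", pos = seq_len(n),
    window = vapply(seq_len(n), function(i) {
      # plant C at -1 only for high-stoichiometry sites
      if (nc[i] > 0.5) window_with(`-1` = "C", `1` = "A")
      else window_with(`-1` = "A", `1` = "A")
    }, character(1)),
    non_conversion = nc, stringsAsFactors = FALSE)
  fr <- baseFreqByBins(wins, n_bins = 20L)
  expect_identical(dim(fr), c(20L, 81L, 4L))
  # 40 sites over 20 bins = 2 per bin; frequencies sum to 1
  expect_equal(apply(fr, c(1, 2), sum), matrix(1, 20, 81),
               ignore_attr = TRUE)
  c_at_m1 <- fr[, "-1", "C"]
  expect_true(all(diff(c_at_m1) >= 0))
  expect_equal(unname(c_at_m1[1]), 0)
  expect_equal(unname(c_at_m1[20]), 1)
  expect_error(baseFreqByBins(wins[1:10, ], n_bins = 20L), "fewer")
})

test_that("group comparison matches an independent Welch formula", {
  expect_equal(compareGroups(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$tests$t, 0)
  expect_equal(compareGroups(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$tests$p_value, 1)
  sep <- compareGroups(c(0, 0, 0, 0, 1, 1, 1, 1),
                       rep(c("lo", "hi"), each = 4))
  expect_true(sep$tests$degenerate)  # zero variance in both groups
  set.seed(7)
  x <- rnorm(10); y <- rnorm(10, 1)
  res <- compareGroups(c(x, y), rep(c("x", "y"), each = 10))
  # textbook Welch statistic computed independently
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / 10 + var(y) / 10)
  dfw <- (var(x) / 10 + var(y) / 10)^2 /
    ((var(x) / 10)^2 / 9 + (var(y) / 10)^2 / 9)
  pw <- 2 * pt(-abs(tw), dfw)
  expect_equal(res$tests$t, tw)
  expect_equal(res$tests$df, dfw)
  expect_equal(res$tests$p_value, pw)
  expect_error(compareGroups(1:3, rep("a", 3)), "2 groups")
})

test_that("motif-determined stoichiometry is recovered in group comparison", {
  # simulate sites whose motif class sets the generated stoichiometry:
  # SSCA_GC high, BA/BBCA_BW middle, VA_RR low
  set.seed(8)
  mk <- function(motif, n, mu) {
    win <- switch(motif,
      SSCA_GC = window_with(`-3` = "C", `-2` = "G", `-1` = "C", `1` = "A",
                            `2` = "G", `3` = "C"),
      BBCA_BW = window_with(`-3` = "T", `-2` = "T", `-1` = "C", `1` = "A",
                            `2` = "T", `3` = "A"),
      VA_RR = window_with(`-1` = "A", `1` = "A", `2` = "G", `3` = "G"),
      BA = window_with(`-3` = "A", `-2` = "A", `-1` = "T", `1` = "A",
                       `2` = "C", `3` = "T"))
    data.frame(window = win, motif = motif,
               nc = pmin(1, pmax(0, rnorm(n, mu, 0.05))))
  }
  d <- rbind(mk("SSCA_GC", 40, 0.9), mk("BBCA_BW", 40, 0.6),
             mk("BA", 40, 0.6), mk("VA_RR", 40, 0.2))
  expect_identical(classifyTSSMotif(d$window), d$motif)
  res <- compareGroups(d$nc, d$motif)
  means <- setNames(res$summary$mean, res$summary$group)
  expect_gt(means["SSCA_GC"], means["BBCA_BW"])
  expect_gt(means["SSCA_GC"], means["BA"])
  expect_gt(means["BBCA_BW"], means["VA_RR"])
  expect_gt(means["BA"], means["VA_RR"])
  p <- res$tests$p_value[res$tests$group1 == "SSCA_GC" &
                         res$tests$group2 == "VA_RR"]
  expect_lt(p, 1e-6)
})

test_that("pattern configs round-trip into the classifier", {
  path <- tempfile()
  writeLines(c("# custom elements",
               "BREu -38:S -37:S -36:R -35:C -34:G -33:C -32:C"), path)
  pats <- readPatternConfig(path)
  expect_named(pats, "BREu")
  w <- window_with(`-38` = "C", `-37` = "G", `-36` = "A", `-35` = "C",
                   `-34` = "G", `-33` = "C", `-32` = "C", `1` = "A")
  expect_identical(classifyTSSMotif(w, patterns = pats), "BREu")
})
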