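---
title: "Quantifying m6Am stoichiometry at single transcription-start nucleotides"
author: "m6AmQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying m6Am stoichiometry at single transcription-start nucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6AmQuant)
```

## The measurement

mRNA 5' ends frequently begin with 2'-O-methyladenosine (Am), and a writer
methyltransferase (PCIF1) converts a large fraction of these to
N6,2'-O-dimethyladenosine (m6Am). m6AmQuant implements a conversion-sequencing
readout of this mark at single-nucleotide resolution: sodium nitrite deaminates
unmethylated A to inosine, which reverse transcription reads as G, while
N6-methylated A resists deamination and is still read as A. After cap-specific
enrichment of transcript 5' ends, the first transcribed base of every molecule
is sequenced directly, so for a reference-A transcription-start nucleotide
(TSN) the *non-conversion rate*

$$\hat{p} = \frac{n_A}{n_A + n_G}$$

is a direct, per-isoform estimator of m6Am stoichiometry. The same quantity at
read-body positions estimates internal m6A. Everything else in the package --
the simulator, the three-base aligner, coverage tiers, gene summaries,
promoter-motif analyses, expression normalization -- exists to compute,
validate or interpret this ratio.

## The library structure and preprocessing

Read 1 begins with an 8 or 11 nt UMI followed by a fixed ATAT spacer; the base
immediately after the spacer is the TSN. `extractUMI()` accepts only pairs
whose spacer matches exactly, moves the UMI into the read name, and strips
UMI + spacer from mate 1. Exact spacer matching is a deliberate choice: the
spacer anchors the TSN coordinate, and a tolerant match risks shifting the
single most important base of the read by up to the allowed mismatch length.
The cost is a slightly conservative yield. Quality trimming uses the standard
cutadapt partial-sum algorithm (Q20, minimum mate-1 length 32 nt), and is a
fixed point: trimming twice changes nothing.

## Three-base alignment and disambiguation

Converted reads no longer match the reference: every A in read 1 may appear as
G. Alignment therefore happens in a reduced alphabet. The reference is
converted twice -- A-to-G for the plus strand, T-to-C for the minus strand --
and reads are converted in silico the same way (read 1 A-to-G, read 2 T-to-C)
before placement. The original base calls are kept aside and restored after
placement, so the A-versus-G status at every reference position survives.

The built-in aligner is deliberately small: exact, end-to-end, ungapped
placement of both mates on both converted references, scored as
0 for a perfect pair with a fixed penalty (default 6) per mismatch. It is
intended for desk-scale genomes and is checked in the test suite against a
brute-force scan over every placement. Real genomes, with splicing and
repeats, should be aligned externally; `importAlignmentsSAM()` accepts a text
SAM with restored sequences, scores and UMIs, and everything downstream is
identical. Gap penalties are accepted for the external path; the built-in
route never emits gaps and the simulator never generates indels.

Because the reduced alphabet makes distinct loci easier to confuse, a unique
placement is accepted only when the best pair score is above -10 *and* beats
the runner-up by more than 9. Both thresholds are strict inequalities;
equal-scoring co-optimal placements -- including the same locus hit on both
strand references -- yield no assignment. Alignments whose mate 1 carries a 5'
softclip are discarded entirely, because a clipped 5' end means the TSN base
was not anchored. PCR duplicates are collapsed by exact UMI at identical
(chromosome, strand, mate-1 5' coordinate); the representative is the
highest-scoring alignment, ties broken by read id so reruns are
deterministic. The tie-break rule is our choice, made for determinism.

## Coverage tiers and precision

A stoichiometry estimate from $n$ reads has granularity $1/n$. Sites are
therefore tiered: *discovery* at >= 20 unique reads (precision 0.05),
*quantified* at >= 50 (precision 0.02); sites below 20 reads are kept only in
raw output. Replicates are merged by summing base counts *before* the ratio
is recomputed -- a pooled-count ratio, not a mean of per-replicate ratios --
which weights replicates by the evidence they carry and makes merging
commutative.

## Gene-level summaries

A TSN is assigned to a gene when an annotated TSS lies within 100 nt
(inclusive) on the same strand; competing annotations are resolved by biotype
priority (snRNA > snoRNA > protein-coding > lncRNA > others), then distance,
then gene id. The inclusive boundary is our reading of a rule stated both as
"within 100 bp" and "< 100 nt" in the method literature; boundary cases are
rare and deterministic.

The per-gene *m6Am gene index* is the read-weighted fraction of
transcription-start events that are m6Am-initiated:
$\sum_s c_s \hat{p}_s / \sum_s c_s$ over the gene's sites, where $c_s$ is site
coverage and $\hat{p}_s$ site non-conversion (non-A sites contribute zero to
the numerator). Read weighting is the default because the phrase "ratio of
m6Am TSNs over all TSNs" is ambiguous between counting reads and counting
sites; an unweighted per-site variant (`weighted = FALSE`) is provided. The
same arithmetic yields the isoform composition of a gene: with A-initiation
fraction $f_A$ and pooled A-site non-conversion $\hat p$, the transcript pool
splits into $f_A\hat p$ m6Am, $f_A(1-\hat p)$ Am and $1-f_A$ non-A-initiated.

## Promoter motifs

Core promoters are examined in an 81-nt window, -40 to +41 around the TSN
(+1 is the TSN; there is no offset 0). A-TSN initiator contexts are classified
against four anchored IUPAC patterns -- SSCA_+1_GC, BBCA_+1_BW, VA_+1_RR and
BA_+1 -- resolved, when several match, in that order. The priority order is
not dictated by the biology; we rank the most constrained pattern first so a
context is always given its most specific label, and the order is
configurable. TATA boxes are the 8-mer TATAWAWR placed entirely inside
-36..-19; the alternative reading ("start anywhere in the region, possibly
overhanging") was rejected because a TATA box truncated by the region edge is
not a TATA box. Additional elements (BREu, BREd, DCE and the like) are not
built in: they are accepted as user-supplied anchored patterns via
`readPatternConfig()`, so the package makes no claim about their consensus
definitions.

## Expression and differential testing

Per-TSN expression is counts of deduplicated molecules, normalized to
transcription-start nucleotides per million (TPM). Cross-sample calibration
uses spiked-in transcripts of constant input and the median-of-ratios
estimator restricted to spike-in rows (computed in log space, the convention
of the count-based differential-expression literature); the test suite checks
it against the DESeq2 control-gene estimator. Differential TSN expression
between conditions is a Welch two-sided t-test on log2(normalized count +
0.5), with fold change log2((mean_B + 0.5)/(mean_A + 0.5)), a baseMean floor
of 100, and BH-adjusted p-values. This deliberately replaces a negative
binomial GLM stack: with two replicates per condition at desk scale a
dispersion-shrinkage model is not estimable in any meaningful way, the
fold-change contract is what downstream analyses consume, and an adapter
(`exportCountMatrix()`) writes the count matrix and design table for users
who want to run an NB-GLM externally. The pseudocount 0.5 is stated and
configurable in the sense that the transformation is exposed; p-values from
this test are not comparable to NB-GLM p-values.

## Internal m6A calling

Read bodies also carry reference-A positions, and their non-conversion
estimates internal m6A. The caller follows a cascade of gene-specific
filters: genes need >= 1000 A+G observations to define a background
non-conversion rate; reads with more than three non-converted A's are
discarded as conversion failures (exactly three is kept); a site is called
when it has >= 20 reads, non-conversion strictly above 0.1, a one-sided
binomial tail $P(X \ge n_A \mid n_A + n_G, p_{bg})$ below 0.05, and no
conversion-resistant-region flag. That flag is the one genuinely
underdetermined rule in the cascade ("more than 5% signals" in the source
literature does not define its denominator); we implement it as: the pooled
non-conversion of all *other* reference-A positions inside the reads covering
the site exceeds 5%. The logic is isolated in one place in
`callInternalM6A()` so alternative readings can be swapped. The one-sided
alternative is used because the question is always excess non-conversion
above background. TSN positions are excluded from the body pileup -- they
belong to the TSN quantifier.

## What the simulator emulates, and what it does not

`simulateLibrary()` generates the study conditions every claim above is
tested against: multi-isoform genes with per-isoform TSN identity and
expression weights, per-A-TSN m6Am stoichiometry, internal m6A marks,
complete or partial nitrite conversion (defaults: conversion rate 1.0 for
unmethylated A, reflecting complete conversion of unmethylated standards;
methyl protection 0.99, mirroring the >95% purity of methylated cap analogs),
spike-in contigs, PCR duplicates (geometric copy counts sharing the parent
UMI), and enrichment leakage -- a default 2% of molecules entering the
library from uniform internal 5' ends, emulating fragments that survive cap
enrichment. Inosine is emitted directly as G because downstream software only
ever sees sequencer base calls.

Deliberate idealisations: UMIs are drawn without replacement, so exact-UMI
deduplication is lossless and truth-table molecule counts are exactly
recoverable (real libraries have rare UMI collisions); toy transcripts are
unspliced; the error model is uniform substitution (default 0) with constant
Q40 qualities otherwise; fragment lengths are fixed; and there is no model of
the capping enzymology itself. Passing tests therefore demonstrate the
correctness of the arithmetic and the pipeline contracts under near-ideal
chemistry -- they do not demonstrate robustness to splicing, indels,
context-dependent conversion failure or alignment ambiguity in repetitive
genomes, which is precisely why the external-SAM route exists.

## Numerical choices and degenerate inputs

Non-conversion at A+G = 0 is `NA`, distinct from a true 0. Welch tests on
zero-variance groups are flagged degenerate rather than computed (identical
constant groups report t = 0, p = 1). Quantile bins break ties by coordinate
so equal stoichiometries still split into equal-count bins deterministically.
Coordinates are 1-based closed internally (the R/Bioconductor convention);
BED output is 0-based half-open. All randomness flows from explicit integer
seeds; the same seed yields byte-identical FASTQ, truth tables and stage
outputs.

## Problem sizes used in the checks

The bundled verification runs are sized for a laptop: toy genomes of 2--25
contigs (a few kb each), libraries of a few hundred to 15,000 molecules, and
three-replicate standards runs of 5,000 molecules each (about 1,000 reads per
standard, comfortably above the 500-read floor the benchmark design calls
for, and enough that binomial noise on a standard's pooled estimate is below
0.01). These sizes make every assertion sharp -- 3-standard-deviation
binomial envelopes, exact dedup counts -- while keeping the whole suite fast.

## Known limitations

The built-in aligner is unspliced and ungapped by design. The expression
module's p-values come from a two-sample Welch test, not an NB GLM. The gene
index weights sites by reads by default, which a site-counting reading would
disagree with. The conversion-resistant-region filter implements one of
several defensible readings of an ambiguous rule. Internal m6A calls are
restricted to 5'-proximal windows represented in a cap-enriched library; no
transcriptome-wide internal methylome claim is made.
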