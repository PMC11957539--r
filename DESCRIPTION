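Package: m6AmQuant
Title: Transcription-Start Nucleotide Mapping and m6Am Stoichiometry from
    Nitrite-Conversion 5'-Cap Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a complete desk-scale pipeline for quantifying
    N6,2'-O-dimethyladenosine (m6Am) stoichiometry at single transcription-start
    nucleotides (TSNs) from sodium-nitrite-converted, cap-enriched paired-end
    sequencing libraries. Unmethylated 2'-O-methyladenosine start nucleotides are
    deaminated and read as G, while m6Am resists conversion and is read as A, so
    the per-site non-conversion rate A/(A+G) estimates methylation stoichiometry.
    The package provides a ground-truth library simulator, UMI/spacer read
    preprocessing, three-base conversion-space alignment with score-gap
    disambiguation and base restoration, 5'-end pileup with coverage-tiered
    stoichiometry calls, nearest-TSS gene annotation with biotype priority,
    gene-level m6Am indices and isoform composition, core-promoter initiator and
    TATA-box motif analysis, spike-in-normalized TSN expression with differential
    testing, and a GLORI-style internal m6A caller.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    knitr,
    rmarkdown
biocViews: Epitranscriptomics, Sequencing, Transcription, Coverage, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
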