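Package: chronoaccess
Title: Co-Oscillation of Chromatin Accessibility and Transcription from
    Time-Series ATAC-Seq and RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genome-wide co-oscillation of chromatin accessibility
    and gene transcription from replicated circadian time courses sampled
    under free-running conditions. Classifies accessible chromatin regions
    (ACRs) as genic, proximal or distal relative to gene models, applies
    coefficient-of-variation fluctuation screens with accessibility and
    expression floors, identifies co-oscillation groups by fuzzy c-means
    clustering with core-membership screening and a Spearman
    synchronization filter, partitions synchronized genes into phase-ordered
    clusters, calls genotype-dependent differential accessibility with a
    negative-binomial test, builds motif-based clock regulatory networks
    from position weight matrix scans, and maps cis-regulatory haplotype
    frequencies across geographic groups. A seeded synthetic-data generator
    with planted rhythmic ground truth makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomeInfoDb,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    DESeq2,
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
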