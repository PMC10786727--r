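Package: lnchomex
Title: Cross-Species lncRNA Homology by Conserved Synteny and RBP Motif Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cross-species long noncoding RNA (lncRNA) homologs that
    share both a conserved genomic location (synteny) and a conserved pattern of
    RNA-binding protein (RBP) binding sites. Transcripts are scanned with
    position-weight-matrix motif libraries, overlapping matches are clustered
    into motif blocks, and candidate pairs are aligned by dynamic programming to
    a motif-pattern similarity score (MPSS) with a gap penalty score (GPS) on
    inter-block spacing; significance comes from permutation nulls. Companion
    modules compute flanking-anchor synteny features with a random-forest
    classifier, downstream conservation and enrichment statistics, paired-crRNA
    knockout-screen design filters with robust-rank-aggregation scoring, and
    seeded synthetic-data generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    tools,
    randomForest,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
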