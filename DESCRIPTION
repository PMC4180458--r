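Package: nsrseq
Title: Not-So-Random Hexamer Primer Design and ncRNA Profiling for
    rRNA-Depleting RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the 'not-so-random' (NSR) priming strategy for
    strand-specific RNA-seq without a separate rRNA depletion step.
    Enumerates hexamer (k-mer) primer candidates, filters those with a
    perfect match to an rRNA reference, emits adapter-bearing oligo
    sheets, and evaluates transcript coverage of the surviving set.
    Downstream, it classifies read alignments into genomic categories,
    computes RPKM, assesses priming bias against external spike-in
    ladders (ERCC-style), calls two-fold differential non-coding RNAs
    between conditions, detects genomic clusters of differential loci,
    scans promoter windows for degenerate IUPAC motifs such as the
    p53/CEP-1 response element RRRCWWGYYY, and provides a 2^-ddCt qPCR
    fold-change calculator. A deterministic synthetic-data generator
    produces fully self-contained fixtures with a ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    digest,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
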