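Package: tssmap
Title: Bacterial Primary-Transcriptome Mapping from Read 5' Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls transcription start sites (TSS) from the 5' ends of mapped
    RNA-seq reads, classifies them against a minimal-transcription-unit model
    into six genomic-context categories (mRNA, leaderless, putative-mRNA,
    internal sense, cis-antisense, trans-encoded sRNA), merges antisense and
    intergenic TSS contigs into asRNA/sRNA features, discovers leaderless and
    Shine-Dalgarno open reading frames guided by TSS using a nearest-neighbour
    RNA:RNA hybridisation energy for the ribosome binding site, predicts
    sigma-factor promoters by an iterative two-phase position-specific scoring
    matrix procedure with exact P-values and by one-mismatch consensus string
    search, and scans for gapped transcription-factor binding motifs. A
    synthetic-genome generator plants all six TSS classes, promoters,
    Shine-Dalgarno leaders and binding sites with simulated read-start pileups
    so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
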