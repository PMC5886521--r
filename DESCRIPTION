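Package: rexreg
Title: Rex Regulon Prediction and Fermentation Physiology Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binding sites of the redox-sensing transcriptional
    repressor Rex in bacterial genomes by scanning both strands for a
    degenerate 18-bp palindrome (a 5-bp AT-rich arm, an 8-bp AT-rich spacer
    with at most one G/C, and the reverse-complement arm with at most one
    mismatch in its last two positions), annotates hits against gene
    features with the upstream-distance and annotation filters used for
    regulon calling, and builds threshold consensus sequences. Also
    implements the companion resequencing and physiology calculators:
    wild-type background subtraction and breakpoint-evidence filtering for
    structural-variant calls, coding-effect nomenclature, percent
    theoretical ethanol yield, sliding-window maximal growth-rate fitting
    from OD600 series, alcohol-dehydrogenase specific activity, and
    absolute qPCR quantification against a standard curve normalized to a
    reference gene. A seeded synthetic-data module generates truth-labeled
    genomes, annotations, growth curves, breakpoint, fermentation and qPCR
    tables so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    S4Vectors,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
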