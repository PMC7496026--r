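Package: promdiverge
Title: Base-Resolution Comparative Analysis of Orthologous Promoter Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing orthologous promoter sequences between closely
    related genomes at base resolution. Extracts transcription start site (TSS)
    anchored promoter windows, classifies promoters as CpG-island or
    non-CpG-island from G+C content and CpG observed/expected score, refines
    candidate ortholog pairs into global pairwise alignments, measures
    dinucleotide alteration spectra and CpG deamination fates, detects and
    characterizes insertions/deletions with a flank-conservation filter,
    associates indels with tandem and inverted repeats via dot plots, scans
    core-promoter motifs (initiator consensus, TATA box), and simulates
    orthologous promoter-pair cohorts with complete mutation ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
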