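Package: tfrctx
Title: Genome-Context Prediction of Regulatory Targets for TetR-Family Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts regulatory targets of TetR-family transcriptional
    regulators (TFRs) from bacterial genome annotation alone. Classifies each
    TFR gene's orientation relative to its immediate neighbors into divergent,
    operonic, and other contexts, computes intergenic separations between
    translational start sites, and applies a configurable distance rule
    (default 200 bp) to call likely regulatory pairs. Categorizes predicted
    target gene products (enzymes by EC class, membrane transporters by
    family, other proteins, unknowns), discovers candidate palindromic
    operator sites in the intervening DNA by inverted-repeat scanning and
    degenerate IUPAC consensus matching, and generates synthetic annotated
    replicons with planted ground truth for end-to-end validation. Reads
    GenBank flat files and GFF3 with FASTA; writes TSV, BED, FASTA, and JSON
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
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
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
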