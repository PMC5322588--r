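Package: barcodegap
Title: Barcode Gap and Probability of Correct Identification Analysis for
    Fungal ITS Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates the complete nuclear ribosomal ITS region and its ITS1
    and ITS2 sub-regions as DNA barcode markers at the genus level. Provides a
    metadata curation cascade for voucher-backed sequence sets (ambiguity,
    naming, region-completeness, length and locality filters), an anchor-motif
    splitter for the ITS1/5.8S/ITS2 partition, per-genus uncorrected p-distance
    matrices from pairwise global alignments, the probability of correct
    identification (PCI) statistic, boxplot-based barcode-gap classification
    with marker group assignment, cross-marker summary statistics, and a seeded
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
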