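Package: dicodon
Title: Massively Parallel Reporter Analysis of Codon-Pair Effects on mRNA Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing massively parallel
    reporter assays that measure how tandem codon-pair repeats affect
    steady-state mRNA levels in budding yeast. Includes enumeration of the
    4096-member codon-pair repeat library, a deep mutational scanning design
    for the (FK)8 stalling repeat, endogenous ORF fragment selection,
    stop-free VNN barcode generation, barcode-to-insert linkage with
    collision filtering, UMI-aware barcode and insert counting, bootstrapped
    log2 cDNA/gDNA quantification with median, spike-in and RPM
    normalisation, codon stability coefficients, dipeptide-level matrices,
    reading-frame rotation comparisons, genotype regression comparisons, and
    position-wise rank-sum tests. A synthetic read simulator with known
    ground truth makes every stage testable without external data.
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
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
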