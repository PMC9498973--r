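Package: barcodekit
Title: DNA Barcoding Analysis of ITS Sequences for Species Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tidy toolkit for ITS (internal transcribed spacer) DNA-barcoding
    analysis of closely related plant species: deterministic center-star multiple
    alignment of near-identical barcode sequences, ITS1/5.8S/ITS2 region
    statistics, haplotype collapsing, variable and species-diagnostic site
    detection, Kimura 2-parameter distance structure with barcode-gap summaries,
    neighbor-joining and K80 maximum-likelihood trees with bootstrap supports and
    species-monophyly assessment, and a seeded synthetic-data generator with
    machine-readable ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
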