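Package: nbsfam
Title: Genome-Wide Analysis of NBS-Encoding Resistance Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide identification and comparative analysis of
    NBS-encoding (NB-ARC) plant disease-resistance gene families. Identifies
    family members from domain evidence (built-in signature and profile
    scanning plus a coiled-coil consensus), classifies genes by domain
    architecture (TNL, CNL, and truncated variants), calls physical gene
    clusters and tandem duplicated arrays, chains collinear synteny blocks
    between genomes to account for gene retention and loss after whole-genome
    triplication, estimates selection pressure on ortholog pairs with
    Nei-Gojobori (1986) Ka/Ks, and quantifies expression divergence of
    ortholog and paralog pairs. A synthetic multi-species genome simulator
    with planted truth tables supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
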