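Package: tandemarch
Title: Tandem-Repeat Inventory and Genome Architecture of Linear Megabase
    Extrachromosomal Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inventories maximal perfect tandem repeats in linear genomes,
    canonicalises them to primitive repeat units, classifies repeat regions as
    genic or intergenic with unit-length divisibility by three, and summarises
    cohorts of genomes with per-genome and pooled statistics. Also detects
    terminal inverted repeats of linear replicons, quantifies normalized
    gene-position conservation across genomes, profiles multicopy protein
    subfamilies, and ships a seeded synthetic-cohort simulator with planted
    ground truth so every stage of the pipeline is testable at desk scale.
    Designed around the genome architecture of Borg extrachromosomal elements
    of Methanoperedens archaea and of giant eukaryotic viruses, but applicable
    to any cohort of linear genomes with gene annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
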