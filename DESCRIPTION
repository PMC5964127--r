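Package: aggcall
Title: Single-Molecule Genotyping of FMR1 CGG Repeat Structure and AGG
    Interruptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the exact CGG repeat structure of both X-linked
    FMR1 alleles of a female from barcoded high-accuracy single-molecule
    amplicon reads. Decomposes each read into triplet blocks (repeat
    length, AGG interruptions, non-canonical interruptions such as CTG),
    demultiplexes pooled runs by barcode, phases reads into one or two
    allele clusters with a consensus structure per allele, classifies
    alleles (normal, intermediate, premutation, full mutation), and maps
    premutation alleles to an AGG-informed risk of expansion to a full
    mutation for genetic counseling. Includes a seeded read simulator
    with a configurable substitution/indel error model so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
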