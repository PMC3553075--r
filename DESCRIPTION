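Package: plastomes
Title: Comparative Plastome Architecture and Rare Genomic Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid genome architecture in
    a phylogenetic context. Detects the inverted repeat and derives the
    quadripartite (LSC/IRa/SSC/IRb) partition of annotated circular plastomes,
    extracts inverted-repeat junction adjacencies and classifies boundaries
    against the ancestral land-plant arrangement, builds gene and intron
    presence-absence character matrices with positional intron nomenclature,
    and maps rare genomic structural changes (gene and intron losses, intron
    gains, inverted-repeat expansions, inversions) onto candidate topologies
    with Fitch and Dollo parsimony, including regraft-based placement
    scanning. Ships a curated ten-taxon lycophyte and fern content matrix and
    a synthetic plastome simulator that plants structural events along a
    known tree with a replayable truth log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
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
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
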