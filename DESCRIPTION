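Package: halideminer
Title: Genome Mining for Alkyl-Halide-Activating Enzyme Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reference-anchored pipeline for discovering CylK-like
    alkyl-halide-activating enzymes in sequenced genomes. Provides
    affine-gap global pairwise alignment against parent reference
    sequences, an identity gate, a dual-domain architecture filter
    anchored at the inter-domain junction residue, catalytic-residue
    equivalence mapping, gene-neighborhood co-localization with partner
    halogenase and monoalkylresorcinol-synthase genes, and a
    neighbor-joining phylogenetic summary with nonparametric bootstrap.
    A synthetic-data generator with a full ground-truth manifest makes
    every stage testable without any sequence downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
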