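Package: phagetax
Title: Genetic-Code-Aware Genomic Taxonomy for Megaphages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying uncultured megaphage genomes into a ranked
    taxonomy from genome sequence alone. Detects stop-codon reassignment
    (translation table 15, TAG reassigned to glutamine) via the coding-capacity
    differential between candidate genetic codes, predicts open reading frames
    under the assigned code, builds a code-aware pangenome by connected-component
    protein clustering at an amino-acid identity threshold, computes fragment-based
    intergenomic similarity (average nucleotide identity multiplied by the aligned
    fraction), infers a concatenated core-protein phylogeny with bootstrap support
    and midpoint rooting, and applies species/genus/family demarcation rules to
    produce nested rank assignments. Includes a synthetic megaphage-clade
    simulator with known taxonomy, genetic code, pangenome structure and pairwise
    divergence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
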