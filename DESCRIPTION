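Package: hapnet
Title: Mitochondrial Haplotype Diversity, Differentiation and Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for population-genetic analysis of aligned
    haploid (mitochondrial) sequence data: haplotype collapsing and frequency
    spectra, Kimura 2-parameter distances with site-bootstrap standard errors,
    Nei haplotype and nucleotide diversity, pairwise Fst and AMOVA-based
    Phi-st with permutation significance, median-joining haplotype networks,
    and deterministic strict-clock divergence dating over a mutation-rate
    grid. Includes a structured-coalescent simulator of aligned haploid
    datasets with known parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
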