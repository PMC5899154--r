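Package: tadloop
Title: TAD Boundary Insulation, Super-Loop Significance, and Insertion
    Mapping from Hi-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locus-scale analysis of binned Hi-C contact
    matrices: insulation-score computation with delta-vector TAD boundary
    calling and boundary-strength scoring, inter-TAD interaction
    comparison, CTCF peak-density sliding windows, a bin-by-bin
    sliding-window t-test for long-range (super-loop) interactions with
    one-way ANOVA comparison of p-value densities, pairwise super-loop
    quantification, and transgene insertion-site detection from
    cassette-to-genome inter-chromosomal contacts. Includes a synthetic
    contact-map generator (power-law distance decay, TAD blocks, focal
    loops, locus deletions, insertion pileups, Poisson depth noise) that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
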