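Package: mitoasym
Title: Strand Asymmetry Analysis of Vertebrate Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing strand-asymmetric nucleotide composition in
    annotated vertebrate mitogenomes. Computes AT and GC skew at
    fourfold-degenerate third codon positions of each protein-coding gene,
    locates the Control Region and its polarity by scanning non-coding
    regions for the CSB-II conserved sequence block, types gene-order
    rearrangements (shuffling, translocation, inversion, duplication)
    against the standard vertebrate architecture, and classifies each genome
    as standard, reversed, disrupted or undetermined according to whether
    per-gene skew signatures match the expectation set by each gene's coding
    polarity relative to the Control Region. Includes a deterministic
    synthetic-mitogenome simulator with known ground truth for validation,
    and an end-to-end pipeline with tabular outputs.
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
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
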