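Package: lzce
Title: Lempel-Ziv Complexity-Entropy Analysis of Symbolic Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of entropy rate and excess entropy for symbolic
    sequences via the exhaustive Lempel-Ziv (LZ76) factorization, with
    block-shuffle surrogates, complexity-entropy diagrams, and a
    level-wise decomposition of information and excess-entropy gains
    across organizational levels (sentences, words, characters, or
    fixed-width units such as codons).  Includes the canonical
    27-symbol text filtering pipeline, seeded surrogate generators,
    synthetic sources with known entropy rates for validation, and
    plain-text/FASTA input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stringi,
    seqinr,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
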