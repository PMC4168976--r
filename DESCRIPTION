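Package: tifa
Title: Transposon Insertion Frequency Analysis for Gene Essentiality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bias-aware statistical calling of gene essentiality from
    transposon insertion sequencing (Tn-seq) data generated with
    TA-targeting mariner-family transposons such as miniHimar. Models the
    chromosomal location bias and the flanking-sequence (6-mer motif)
    preference of the transposon, computes per-gene Poisson-binomial
    insertion probabilities through a probability generating function,
    and calibrates essential and nonessential call cutoffs to a fixed
    expected number of false positives, with Monte Carlo self-validation.
    Includes operon polar-effect filtering of essential calls, a flux
    balance analysis comparator for genome-scale metabolic model
    validation, and a synthetic library generator with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    quadprog,
    rtracklayer,
    optparse
Config/testthat/edition: 3
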