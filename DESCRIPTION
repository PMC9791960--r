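Package: polyfam
Title: Gene-Family Characterization in Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for genome-wide characterization of a
    gene family in an allopolyploid genome, modelled on the workflow used for
    PHD-finger (Cys4-His-Cys3 zinc finger) genes in hexaploid wheat. Provides
    similarity-search plus domain-scan family identification with sequential
    naming in chromosomal order, ProtParam-style protein statistics,
    neighbor-joining phylogenies with Poisson-corrected distances and bootstrap
    supports, collinear-block detection with tandem/segmental duplication
    typing, homoeolog A:B:D triad classification, Nei-Gojobori (1986) Ka/Ks
    estimation with molecular-clock divergence dating, TPM expression binning
    and differential-expression calling, and 2^(-ddCt) qPCR analysis. A
    synthetic-data module generates polyploid genomes, diverged codon pairs,
    expression matrices and Ct tables with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
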