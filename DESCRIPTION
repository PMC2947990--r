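Package: sterileX
Title: Testis Expression Analysis of Fertile and Sterile F1 Hybrid Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable reimplementation of a whole-testis microarray expression
    analysis contrasting fertile and sterile F1 hybrid male mice from a reciprocal
    cross between Mus musculus and M. domesticus. Covers probe-level
    perfect-match/mismatch detection calls, robust probe summarization, quantile
    normalization, gene-by-gene equal-variance t contrasts with exhaustive
    sample-relabeling FDR estimation, hierarchical definition of
    sterility-correlated gene sets with three-way direction binning,
    chromosome-wise hypergeometric and cell-class binomial enrichment stratified
    for the X chromosome, the cellular-composition confound model with its
    robust-gene filter, chromosome-wide expression deviation profiles with
    X-versus-autosome distribution shift tests, and X-versus-autosome comparison
    of protein evolutionary rates. Includes a seeded synthetic testis-expression
    generator with an explicit spermatogenic cell-type mixture model so the whole
    pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
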