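Package: refstab
Title: Reference Gene Stability Analysis for qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for selecting stable reference genes for qPCR
    normalisation. Implements the four standard stability algorithms
    (BestKeeper consensus correlation, geNorm iterative M-value
    elimination with pairwise variation, NormFinder model-based variance
    decomposition with grouped analyses, and the comparative deltaCt
    method), an integrated geometric-mean-of-ranks consensus, and
    validation of multi-gene normalisation factors by within-group
    coefficient of variation. Includes tidy readers for long and wide Cq
    tables, Cq-to-relative-quantity conversion, canonical study
    subsetting, and a seeded synthetic Cq generator emulating a factorial
    tendon-injury study design for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
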