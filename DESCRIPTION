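Package: meripdiff
Title: Differential m6A Methylation Analysis for MeRIP-seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects condition-dependent changes in m6A(m) peaks from
    MeRIP-seq experiments while controlling for gene-expression changes.
    Fits a per-peak negative-binomial generalized linear model with an
    IP-by-condition interaction term and tests it with a chi-squared
    (df = 1) likelihood-ratio test, using library-size offsets and two
    dispersion-estimation variants. Also provides Poisson versus
    negative-binomial goodness-of-fit assessment by parametric bootstrap,
    peak reproducibility and saturation metrics, DRAC motif enrichment,
    replicate-subsampling power analysis, and a synthetic-data generator
    that emulates paired IP/input count structure with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    GenomicRanges,
    IRanges,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    Rsamtools,
    S4Vectors,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
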