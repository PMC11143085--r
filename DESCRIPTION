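Package: polarploidy
Title: Trisomic-Baseline Aneuploidy Calling for Pooled Polar Bodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Copy-number calling for preimplantation genetic testing for
    aneuploidy (PGT-A) on pooled first and second polar bodies, where the
    euploid expectation is three chromatids per chromosome rather than two.
    Implements low-pass nanopore read ingestion with mapping-quality
    filtering, fixed- and variable-width binning with quantile masking and
    GC correction, a zero-inflated negative-binomial hidden Markov model
    over 0- to 4-somy states anchored to a 3-somy baseline, 10-Mb segment
    filtering and per-chromosome ploidy calls; the matching trisomic-baseline
    aCGH log2-ratio threshold classifier with the DLR-spread quality metric;
    cross-method concordance tables; and a seeded simulator of WGA-like
    single-cell coverage and aCGH probe profiles that provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
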