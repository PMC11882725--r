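Package: genomicg
Title: Genomic g Extraction and g-Corrected GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing a genomic general factor ("genomic g") from
    multi-trait GWAS summary statistics and for characterizing how the
    genetic correlation landscape changes after the correction. Implements
    LD score regression with block-jackknife sampling covariances, assembly
    of the genetic covariance matrix S and its sampling matrix V, a
    one-common-factor structural model fit by diagonally weighted least
    squares with sandwich standard errors, per-SNP residualization paths
    (GWAS-by-subtraction) producing g-corrected summary statistics, and
    pre/post comparison of genetic correlation matrices. Includes a
    truth-known simulator of multi-trait summary statistics with LD-block
    structure so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
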