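Package: methage
Title: Count-Based Maximum-Likelihood Estimation of Epigenetic Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Epigenetic age prediction from bulk bisulfite sequencing
    counts. Per-CpG methylation-age reference curves are fit by locally
    weighted regression (LOWESS) or ordinary least squares, candidate sites
    are ranked by Spearman correlation with age, and a subject's age is
    estimated by maximising the binomial log-likelihood of its observed
    cytosine/thymine read counts over a discrete age grid. Includes
    parametric-bootstrap interquartile uncertainty bounds, readers for
    CGmap and Bismark coverage files, a synthetic cohort generator with
    nonlinear methylation-age trends, read downsampling, and a k-fold
    cross-validation harness with residual-bias diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
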