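Package: kscfs
Title: Two-Stage Gene Selection with the Kolmogorov-Smirnov Test and
    Correlation-Based Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects discriminative genes from binary-class expression
    matrices in two stages: a per-gene two-sample Kolmogorov-Smirnov
    filter retains genes whose class-conditional distributions differ at
    a chosen significance level, and correlation-based feature selection
    (CFS) with best-first search then removes redundancy from the
    candidate set. Includes Wilcoxon rank-sum and Welch t univariate
    filters, mRMR and ReliefF rankers with wrapper-style forward
    selection, cross-validated linear support-vector-machine evaluation
    of gene subsets with a repeated-shuffle protocol, CSV/TSV/ARFF
    input-output, and a synthetic expression-data generator with planted
    informative, redundant, and noise genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
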