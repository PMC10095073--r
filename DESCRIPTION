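Package: driverprog
Title: Patient-Specific Cancer Driver Scoring and Prognosis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-specific weighted gene networks from tumor-versus-normal
    expression rank differences and somatic mutations, scores genes by a
    per-gene-damped network propagation (a modified personalized PageRank),
    corrects scores with a mutation penalty and converts them to win rates, and
    trains a small feed-forward neural network to separate good- from
    poor-prognosis patients. Includes cross-validated t-test gene selection,
    repeat-experiment evaluation with network and feature ablations,
    prognostic-gene frequency summaries with subnetwork edge density, and a
    synthetic cohort generator with planted prognostic structure for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
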