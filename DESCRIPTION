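Package: bonetex
Title: CT Texture Analysis for Opportunistic Bone Mineral Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates bone mineral content (BMC) and bone mineral density
    (BMD) from the texture of trabecular bone in axial CT slices. Extracts a
    45-feature radiomic signature per region of interest (5 histogram
    statistics plus 40 gray-level co-occurrence matrix statistics over two
    directions and four gray-level quantizations), fits z-score-normalized
    linear regressors by normal equations via pseudoinverse as well as
    L1-penalized (LASSO) regressors by coordinate descent, and regresses
    longitudinal BMC change from a 90-feature two-timepoint design. Includes a
    synthetic trabecular-phantom cohort generator with known ground truth so
    the whole pipeline is testable end to end, broom-style tidiers, ggplot2
    plotting methods, and a reproducible one-call pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
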