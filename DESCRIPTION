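Package: mrmediate
Title: Two-Sample and Two-Step Mendelian Randomization with Mediation
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: instrument selection (genome-wide significance filtering,
    greedy LD clumping, outcome-association exclusion, F-statistic
    instrument-strength diagnostics), exposure-outcome allele harmonization
    with palindromic-variant handling, causal-effect estimation
    (inverse-variance weighted with multiplicative random effects, MR-Egger
    slope and intercept, weighted median with bootstrap standard errors),
    and sensitivity analysis (Cochran's Q, leave-one-out, funnel data,
    MR-PRESSO global and per-instrument outlier tests). A two-step
    mediation layer decomposes a total effect into direct and indirect
    components by the product-of-coefficients method with delta-method
    standard errors and proportion mediated. A summary-statistics simulator
    with known causal structure, pleiotropy and block LD makes every stage
    testable without external GWAS downloads. Results are tibbles with
    broom-style tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
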