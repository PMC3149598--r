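Package: crctsize
Title: Design Calculations for Cluster Randomised Trials with a Fixed
    Number of Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-size and power calculations for two-arm cluster
    randomised controlled trials in which the number of clusters per arm
    is fixed in advance. Computes the required number of individuals per
    cluster, runs the feasibility check k > n_I * rho * (cv^2 + 1), and,
    for infeasible designs, the minimum detectable difference (MDD) and
    maximum achievable power (MAP) implied by the precision bound
    2 * sigma^2 * rho * (cv^2 + 1) / k as cluster sizes grow without
    limit. Supports continuous and binary outcomes (pooled-variance
    normal approximation), equal or unequal cluster sizes via the
    coefficient of variation, a practical-advice workflow producing a
    structured design report, and a seeded Monte-Carlo engine that
    validates the analytic power formulas against simulated
    cluster-correlated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
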