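Package: gwareal
Title: Geographically Weighted Regression and Random Forests for Areal Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untangling spatial heterogeneity in areal (e.g. county-level)
    health outcomes such as type 2 diabetes prevalence. Implements exploratory local
    spatial statistics (Getis-Ord Gi* hotspots, bivariate local Moran's I with
    conditional permutation inference, geographically weighted Pearson correlation),
    geographically weighted ordinary least squares (GW-OLS) with adaptive bi-square
    kernels, AICc bandwidth selection, dependent-test adjusted p-values and local
    variance inflation factors, geographically weighted random forests (GW-RF) with
    per-location permutation and node-purity importance surfaces, and a cross-validated
    four-model comparison harness (OLS, RF, GW-OLS, GW-RF). A seeded synthetic areal
    data generator with known spatially varying coefficient surfaces provides
    recoverable ground truth for every stage. All user-facing functions take a data
    frame first and return tibbles.
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
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
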