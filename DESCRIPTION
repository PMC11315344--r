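Package: frostgrade
Title: Grading Wheat Freeze-Injury Severity from Canopy Image Color Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies winter-wheat freeze-injury severity (none / mild /
    severe) from the color information in digital canopy images. Extracts the
    20 color-gradation skewness-distribution (CGSD) parameters (mean, median,
    mode, skewness, kurtosis of the R, G, B and gray-level histograms),
    screens them with Kaiser-Meyer-Olkin and Bartlett sphericity tests,
    selects key parameters by factor analysis with principal-component score
    coefficients, and grades samples with a Gaussian naive Bayes classifier
    benchmarked against hierarchical (Ward) and K-means clustering baselines.
    Includes synthetic canopy-image and agrometeorological-series generators
    with severity-dependent structure for end-to-end testing, plus confusion
    matrix and accuracy reporting.
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
    jpeg,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
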