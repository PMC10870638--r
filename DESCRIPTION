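Package: symclust
Title: Symptom Cluster Stability and Consistency Across Age Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the symptom experience of two patient
    groups from multidimensional symptom surveys such as the Memorial
    Symptom Assessment Scale (MSAS). Provides per-group descriptive
    comparisons of symptom occurrence, severity, and distress (Fisher's
    exact, Mann-Whitney, and t tests, top-k rankings with ties),
    estimation of tetrachoric correlation matrices from binary occurrence
    data, exploratory factor analysis by unweighted least squares with
    oblique geomin rotation, extraction of symptom clusters under a
    loading threshold, and classification of cluster stability and top-k
    consistency across groups. A latent thresholded-Gaussian generator
    simulates realistic two-group symptom datasets for validation.
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
    pracma,
    purrr,
    readr,
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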