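Package: socsel
Title: Scale-Dependent Social Context and Social Selection in Sexually
    Polymorphic Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the spatial scale of social context in
    mapped plant populations and for evaluating its consequences under the
    multilevel (social) selection model S_i = P_ii*beta_N + C_ij'*beta_S.
    Maps individuals from three-station range surveys by trilateration,
    computes local sex-ratio neighborhoods at nested radii, quantifies how
    the variance of local hermaphrodite frequency and the covariance between
    an individual's sex and its neighborhood sex ratio (C_ij') change with
    spatial scale, and derives the critical social selection gradient at
    which social selection cancels the fecundity advantage of females in
    gynodioecious species. Includes a Thomas-cluster synthetic population
    generator with spatially autocorrelated sex labels, a label-permutation
    null for the sex/neighborhood covariance, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
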