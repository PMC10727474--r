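Package: acdsim
Title: Spatial Simulation of Autologous Cell Defection in Cancer Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic spatial lattice simulation of cancer clusters invaded by
    engineered defector ("hypertumour") cells, with diffusible cancer growth
    factors, Warburg-effect lactate acidification, one-way oncogene mutation,
    immune surveillance and growth-factor-reducing drugs, under a death-birth
    update rule. Also implements the deterministic four-cell fitness model of
    the hypertumour-cancer interface, including the relative drug effect phi
    and its parameter sweeps for linear, logistic, convex and concave
    growth-factor-to-fitness transformations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
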