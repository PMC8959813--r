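Package: crownarch
Title: Crown and Stem Architecture of Individual Trees from Terrestrial
    Laser Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline from plot-level terrestrial laser
    scanning (TLS) point clouds to tree-level crown and stem architecture
    and treatment-effect statistics. Individual trees are delineated from
    a canopy height model with a variable window filter and
    marker-controlled watershed, points are classified into stem and
    crown, stem taper curves are reconstructed by per-slice circle fitting
    and cubic splines, and convex-hull crown traits are computed,
    including the stem cross-sectional area at the height of the maximum
    crown diameter (SAHMC). A synthetic-stand generator with analytic
    ground truth emulates thinning experiments in Scots pine stands, and a
    statistics layer fits nested two-level linear mixed-effects models
    with Tukey treatment contrasts and trait screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    grDevices,
    utils,
    Rcpp,
    FNN,
    lme4,
    lmerTest,
    multcomp,
    generics,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    readr,
    withr
Config/testthat/edition: 3
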