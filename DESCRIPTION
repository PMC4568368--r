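Package: stereowound
Title: Design-Based Stereology for Wound-Healing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Design-based stereological analysis of experimental wound
    healing: point-grid (Cavalieri-type) wound area estimation, wound
    closure-rate timecourses, volume densities by point counting, optical
    dissector numerical density of fibroblasts, vessel length density from
    profile counts on isotropic uniform random sections, and nonparametric
    group comparison (Kruskal-Wallis, exact Mann-Whitney). Includes a
    synthetic 3D dermis generator (Poisson cell process, Boolean collagen
    and hair-follicle models, isotropic vessel segment process) with known
    ground truth, so every estimator can be validated by parameter
    recovery without raw histological data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
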