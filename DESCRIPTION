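Package: islet3d
Title: Whole-Organ 3D Morphometry of Pancreatic Islets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Volumetric analysis of insulin- and glucagon-labelled pancreatic
    islets in reconstructed 3D image stacks (optical projection tomography or
    light sheet fluorescence microscopy dialects). Provides a synthetic tissue
    phantom generator with ground-truth islet catalogs, two-pass
    gradient-corrected 3D segmentation with tissue-mask exclusion, per-islet
    morphometry (equivalent-sphere diameter, mean 3D diameter, iso-surface
    sphericity), endocrine composition classification under the one-percent
    negativity rule, thirds-of-volume size categories, k-nearest-neighbour
    spatial statistics, robust outlier removal (ROUT), normality-gated paired
    testing, and machine-readable per-disc reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    tiff,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
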