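Package: coldpheno
Title: Image-Based Phenotyping of Maize Seedling Cold-Stress Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how maize seedlings recover from a
    temporary cold stress using side-view RGB images. Provides a naive
    Bayes per-channel colour classifier that labels pixels as background,
    healthy or necrotic tissue, mask cleanup with rack-line exclusion,
    extraction of sixteen morphological traits (height, width, area,
    perimeter, convex-hull and image-moments-ellipse descriptors) plus
    percent necrosis, time-shifted growth-rate statistics with log2 fold
    changes between treatments, per-genotype necrosis ANOVA with Tukey
    HSD, and hierarchical clustering of genotype response fingerprints
    ("phingerprints"). A synthetic plot-image and trait-trajectory
    generator with ground truth makes the full pipeline testable without
    any image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    mclust,
    png,
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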