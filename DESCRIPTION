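Package: exomet
Title: Stationary-Phase Exometabolite Release Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for untargeted LC-MS exometabolomics
    of bacterial cultures sampled over stationary phase. Classifies aligned
    mass-spectral features as released exometabolites with a six-criterion
    temporal filter (control maximum, noise ratio, replicate coefficient of
    variation, minimum at the exponential-phase time point, log2 fold change,
    and Pearson correlation with time), selects an internal-standard reference
    feature and applies cube-root normalization, and runs longitudinal
    composition statistics (Bray-Curtis dissimilarity, principal-coordinate
    analysis, PERMANOVA with seeded or fully enumerated permutations,
    repeated-measures and pairwise variants, Protest, centroid dissimilarity
    trajectories, and per-feature ANOVA with FDR control). Companion stages
    partition released features across strains, attach Metabolomics Standards
    Initiative identification levels, and classify transporter genes against a
    low-expression minimum from RNA-seq counts. A seeded synthetic-data
    generator plants released features, per-criterion decoys, internal
    standards, and transporter gene classes so that every stage is testable
    without raw instrument data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
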