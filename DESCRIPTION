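Package: rhizomarker
Title: Untargeted Rhizosphere Metabolomics Marker Discovery and Supporting Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible pipeline for discovering rhizosphere-enriched
    metabolic markers from aligned untargeted LC-MS feature tables:
    half-minimum imputation, median normalization, cube-root transform and
    Pareto scaling; PCA, NIPALS PLS-DA with cross-validated Q2, and
    Pearson-correlation clustering; Welch volcano statistics with
    fold-change/significance selection, top-k marker pooling and
    ANOVA/Benjamini-Hochberg refinement; adduct and 13C-isotope
    deconvolution with neutral-mass inference and compound-library
    annotation into metabolite-class compositions. Companion statistics for
    the microbial "rhizosphere effect" (OTU prevalence filtering, Shannon
    diversity, rarefaction, Bray-Curtis PERMANOVA) and for root-damage
    controls (relative conductivity, Welch's F-test on ranks, Games-Howell
    post-hoc with compact letter display, CFU t-tests). Seeded synthetic
    generators with known ground truth make every stage testable without
    raw instrument data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
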