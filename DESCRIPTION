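Package: tumoroidtk
Title: Quantifying T-Cell Recruitment, Killing and Motility in ECM-Embedded Tumoroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis and motility toolkit for bispecific-antibody
    (bsAb) mediated T-cell attack on collagen-embedded tumoroids imaged as
    multi-channel 3D time-lapse stacks. Provides per-plane segmentation of
    nuclei, propidium-iodide (PI) objects and T-cells; tumoroid boundary
    masking; whole-tumoroid killing fraction and in-tumoroid T-cell counts;
    volume-gated 3D detection and Hungarian frame-to-frame linking of T-cell
    trajectories; time-averaged mean-squared-displacement (MSD) analysis with
    a directed-plus-diffusive model fit and the diffusive-fraction statistic;
    and a ground-truthed synthetic scenario generator (tumoroid packing,
    two-phase T-cell motility, contact killing, fluorescence rendering) so the
    full pipeline is testable without raw microscopy data. Tibble-first
    interfaces with ggplot2 plotting and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    tiff,
    EBImage,
    yaml,
    jsonlite,
    emmeans,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
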