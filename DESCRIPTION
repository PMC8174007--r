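Package: flyspt
Title: Single-Particle Tracking PALM Analysis for Sparse Photoconvertible
    Fluorophore Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A single-particle tracking PALM (sptPALM) analysis pipeline for
    sparse photoconvertible fluorophore recordings such as mEos2-tagged
    membrane proteins imaged in ex vivo brain tissue. Detects single
    emitters per frame with a scale-normalized Laplacian-of-Gaussian filter,
    median prefiltering and subpixel Gaussian refinement; links detections
    into trajectories by solving a linear assignment problem with
    birth/death alternatives; computes per-track and ensemble mean squared
    displacement, diffusion coefficients from four-point linear fits, and
    mobile-to-immobile fractions; and performs internally controlled paired
    comparisons (baseline-peak normalization, area under the normalized MSD
    curve, delta mobility, maximum-projection Pearson drift QC, and
    nonparametric tests). Includes a ground-truth movie simulator with
    photoconversion/blinking/bleaching kinetics, Gaussian PSF rendering and
    EMCCD-style noise so every stage is verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
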