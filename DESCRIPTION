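Package: fcdecode
Title: Resting-State Functional Connectivity Mapping and Transcriptomic
    Decoding of Over-Connectivity Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for mouse resting-state fMRI group
    studies and their transcriptomic interpretation. Preprocesses 4D BOLD
    time series (volume trimming, despiking, nuisance regression, masked
    spatial smoothing, zero-phase band-pass filtering), computes global and
    seed-based functional-connectivity maps, compares groups voxelwise with
    permutation-based family-wise-error cluster correction, and decodes
    over-connectivity hotspots against regional gene-expression energies
    using dual-region top-quantile selection and minimum-hypergeometric
    ranked enrichment with an exact dynamic-programming p-value, plus a
    random-region-pair specificity control and Fisher's exact gene-set
    overlap statistics. Includes seeded synthetic-cohort and
    expression-matrix generators with planted effects so every stage is
    testable without external data.
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
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
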