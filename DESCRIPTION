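Package: braintropy
Title: Amplitude-Aware Permutation Entropy Analysis of BOLD fMRI
Version: 0.1.0
Authors@R:
    person("braintropy", "developers", email = "braintropy@example.org",
           role = c("aut", "cre"))
Description: Voxelwise amplitude-aware permutation entropy (AAPE) for 4D
    BOLD-like images, aggregated to atlas regions of interest, with
    two-group region-level statistics under Benjamini-Hochberg false
    discovery rate control and covariate-residualized linear-kernel ridge
    prediction of neuropsychological scores with cross-validation. Includes
    a synthetic resting-state cohort generator for validation, a minimal
    NIfTI-1 reader/writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
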