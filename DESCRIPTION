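Package: fcstrength
Title: Voxelwise Functional Connectivity Strength Analysis of MCI-to-AD Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for whole-brain functional connectivity
    strength (FCS) analysis of resting-state BOLD fMRI in the context of
    conversion from mild cognitive impairment (MCI) to Alzheimer's disease
    (AD). Generates reproducible synthetic resting-state cohorts with
    group-graded network coupling, performs temporal preprocessing (linear
    detrend, band-pass filtering, nuisance regression), computes voxelwise
    FCS (thresholded sums of Fisher-z connectivity) and seed-based
    connectivity maps, runs covariate-adjusted group inference with
    Monte-Carlo cluster-extent correction, classifies MCI converters versus
    nonconverters with a leave-one-out cross-validated support vector
    machine, and re-runs the converter comparison under a robustness suite
    (correlation thresholds, framewise-displacement covariate, global
    signal regression on/off).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
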