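Package: graspdecode
Title: Simulation and ROI-Based Multivoxel Pattern Decoding of Event-Related fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for region-of-interest (ROI) multivoxel pattern analysis of
    event-related fMRI experiments contrasting reaching-only and reach-to-grasp
    actions. Provides an event-related BOLD simulator (mini-block designs,
    truncated-exponential stimulus onset asynchronies, double-gamma
    haemodynamic response, AR(1) noise and slow drift), geometric ROI mask
    construction (spheres and cubes in millimetre coordinates), the runwise
    preprocessing chain (standardise, detrend, discrete-cosine high-pass),
    mini-block averaged sample construction, leave-one-pair-out
    cross-validated linear support-vector-machine decoding, and group-level
    inference (one-tailed t-tests against chance with Benjamini-Hochberg
    false-discovery-rate control, repeated-measures ANOVA with partial eta
    squared, paired post-hoc tests, and linear trend contrasts), plus a
    config-driven pipeline that runs the full experiment end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
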