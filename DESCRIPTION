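Package: roimediate
Title: Region-Based Mediation Analysis of Age, Memory, and Sentence Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for testing whether regional brain structure and function
    mediate age-related change in sentence processing. Scores trial-level
    self-paced-reading data into accuracy, relative-clause reading time, and
    structural disadvantage scores; extracts per-region gray-matter-volume
    means and partial amplitude of low-frequency fluctuations (pALFF) from
    volumetric images; and fits three-variable mediation path models with
    nuisance covariates by ordinary or bisquare-robust least squares, with
    bias-corrected bootstrap p-values and per-hemisphere false-discovery-rate
    correction. A synthetic-data module generates cohorts, self-paced-reading
    trials, ROI feature tables with planted mediation effects, and a 4D BOLD
    phantom so the whole pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
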