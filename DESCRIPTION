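Package: adopls
Title: Age-Corrected OPLS Discriminant Analysis of Regional Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-class orthogonal projections to latent structures (OPLS)
    discriminant analysis of regional cortical thickness and subcortical
    volume tables, for separating Alzheimer's disease patients from
    cognitively normal controls and predicting progression in mild
    cognitive impairment.  Implements two age-correction strategies
    (age as a covariate, and linear detrending of each measure against
    age estimated in the control group only), hierarchical modelling of
    volume and thickness blocks, sevenfold cross-validated Q2/R2 model
    assessment, fixed-cutoff classification metrics, characterization of
    correctly versus incorrectly classified subjects, and a seeded
    synthetic cohort generator for end-to-end testing without access to
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
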