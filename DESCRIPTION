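Package: elacohort
Title: Energy Landscape Analysis of Longitudinal Health-Checkup Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for energy landscape analysis (ELA) of longitudinal
    health-checkup data, aimed at stratifying pathways from health to
    diabetes onset. Provides a synthetic cohort generator with known
    latent-state ground truth, diagnosis and obesity labelling rules,
    a multi-step record-filtering pipeline with random-forest feature
    ranking, median binarization of selected biomarkers, maximum-likelihood
    fitting of a pairwise maximum-entropy (Ising) model over 64 binary
    patterns, basin-graph decomposition into stable states, minimax
    energy-barrier (disconnectivity) computation with optional pattern
    restriction, year-to-year state-transition counting, chi-squared
    pathway-preference tests, and Mann-Whitney comparisons of feature
    values in the year before each transition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
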