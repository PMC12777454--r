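Package: schizrec
Title: Similarity-Based Antipsychotic Treatment Recommendation from
    Hospital Admission Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a collaborative-filtering medication
    recommender for hospital in-patients with schizophrenia spectrum
    disorders. Computes a composite treatment "affinity" score from
    admission histories (inter-admission gaps, medication switches,
    length of stay, visit counts), implements five patient-similarity
    engines (cosine and Euclidean collaborative filtering, weighted Gower
    with ReliefF attribute weights, Gaussian RBF kernels, and
    neighbourhood components analysis), and evaluates them with a
    leakage-proof visit-stratified nested patient-grouped
    cross-validation harness. A synthetic cohort generator with a planted
    drug-response structure makes the full pipeline runnable and testable
    without access to credentialed hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
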