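Package: digiphen
Title: Digital Phenotyping of Internalizing Symptoms from Passive Smartphone Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for passive smartphone-sensing studies of youth
    mental health. Ingests raw per-participant sensor event streams (GPS fixes,
    call events, screen on/off events, ambient-light samples), extracts daily
    behavioral features (mobility via Haversine distances, 150 m location
    clusters and normalized location entropy; social interaction from call
    logs; phone use from screen sessions; a sleep proxy from nighttime ambient
    light), scores the SCARED, CES-DC and ASRS self-report instruments, and
    runs covariate-adjusted rank-correlation and nested linear-model analyses
    of symptom-behavior associations. A deterministic synthetic-cohort
    generator with planted symptom-behavior couplings makes every stage
    testable without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    broom,
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
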