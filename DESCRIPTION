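Package: osatriage
Title: Hybrid Fuzzy-Statistical Decision Support for Obstructive Sleep Apnea Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening-stage decision support for obstructive sleep apnea (OSA).
    Two concurrent risk engines are combined: a Statistical Risk from a
    bagged-tree classifier over objective health-record features (anthropometry,
    habits, comorbidities, treatments) and a Symbolic Risk from a three-level
    cascade of seven Mamdani fuzzy expert systems over sleep-interview answers.
    The two risks are mapped to levels via clinical thresholds, converted to
    utility scores, and fused into a decision variable driving a three-way
    recommendation (non-OSA / doubtful / possible OSA). Includes a generic
    Mamdani inference engine with centroid defuzzification, SMOTE-NC class
    balancing for mixed continuous/categorical features, and a seeded synthetic
    cohort generator emulating a sleep-unit population for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
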