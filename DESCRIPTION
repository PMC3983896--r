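Package: caretraj
Title: Temporal Representation of Cancer Care Trajectories from Coded
    Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reconstructs dated care trajectories for cancer patients from
    the coded record streams routinely held by population cancer
    registries.  Hospital-discharge rows (ICD-10 diagnoses with linked
    cancer codes, CCAM procedures) and anatomical-pathology rows (ADICAP
    codes) are classified into tracer events, resolved to one event per
    patient-day, and aggregated into ordered care states (pathology,
    surgery, surgery with pathology, neoadjuvant and adjuvant
    chemotherapy, radiotherapy, concomitant chemo-radiotherapy).  State
    sequences are rendered in a simple form (one character per state) and
    a duration-extended form (one character per calendar day, gaps coded
    "I"), stored vertically in SPELL format, and queried for waiting-time
    indicators and guideline-delay flags.  Reconstructed sequences are
    validated against reference sequences with a generalised Levenshtein
    edit distance, and sequences are classified against the standard
    non-metastatic breast-cancer care pathways.  A synthetic cohort
    generator with configurable coding-anomaly noise supports end-to-end
    evaluation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
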