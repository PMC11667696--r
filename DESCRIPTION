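Package: stilsort
Title: Hierarchical Rank-Sort Case Prioritization for sTILs Annotation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling annotation-study batches from multi-site
    digital-pathology cohorts of triple negative breast cancer. Harmonizes
    patient, whole-slide-image (WSI) and region-of-interest (ROI) metadata to a
    controlled vocabulary, scores each WSI on stromal tumor-infiltrating
    lymphocyte (sTILs) density bins, patient demographics, disease stage and
    annotation pitfalls, ranks cases by a hierarchical (lexicographic)
    rank-sort that enriches underrepresented subgroups, deduplicates to one WSI
    per patient, and assigns the top cases round-robin to fixed-size reader
    batches. Includes diversity diagnostics (Shannon entropy of density bins,
    sample skewness, subgroup retention), summary tables (missingness,
    demographics, stage distribution), a seeded synthetic-cohort generator for
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
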