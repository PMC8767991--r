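Package: icdshift
Title: Interannual Variation Analysis of ICD-10 Coded Primary Care Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying year-on-year shifts in the diagnostic mix of
    primary-care visit registries coded with ICD-10. Visit-level records are
    rolled up through the ICD-10 hierarchy (chapters, blocks, three-character
    categories), aggregated into period-by-code term-frequency matrices, and
    summarised with interannual variation percentages and a normalized
    variation index that weights each code group's contribution to the total
    disruption between two periods. Includes stratified cohort descriptors
    (modality, specialty, age group, sex), a seeded synthetic visit-cohort
    generator calibrated to published registry margins for pipeline testing,
    and deterministic table emission for reporting.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
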