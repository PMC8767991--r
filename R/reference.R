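#' Published reference tables from a two-year Catalan primary-care registry
#'
#' The package ships the published 2019/2020 margins of a Central Catalonia
#' primary-care visit registry (the region's Health Information System
#' covers 32 of its 37 primary-care centres). These printed tables are the
#' only machine-checkable ground truth for the analysis and double as the
#' calibration source for the synthetic-cohort generator:
#'
#' * `"chapters"` — diagnostic-code occurrences per ICD-10 chapter and year
#'   (21 chapters, the full level-1 table).
#' * `"visits"` — cohort descriptors per year: patients, visits by
#'   modality/specialty/age group/sex, total codes.
#' * `"face_to_face_top5"` — the five chapter-format groupings with the
#'   largest variation index among face-to-face visits.
#' * `"telemedicine_top5"` — likewise for telemedicine visits. Note the
#'   published A00-B99 row carries a 2020 count inconsistent with its own
#'   printed total and variation; it is reproduced as printed.
#'
#' @param name Which table to load.
#' @return A tibble with a `label` (or `characteristic`) column and
#'   `n_2019`, `n_2020` count columns.
#' @examples
#' reference_table("chapters")
#' @export
reference_table <- function(name = c(
                              "chapters", "visits",
                              "face_to_face_top5", "telemedicine_top5"
                            )) {
  name <- match.arg(name)
  file <- switch(name,
    chapters = "catalonia_chapter_counts.csv",
    visits = "catalonia_visit_summary.csv",
    face_to_face_top5 = "catalonia_face_to_face_top5.csv",
    telemedicine_top5 = "catalonia_telemedicine_top5.csv"
  )
  path <- system.file("extdata", file, package = "icdshift", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Published headline counts of the reference registry
#'
#' Overall figures printed alongside the reference tables: total visits
#' over both years, visits with at least one diagnosis (as printed in the
#' coded-fraction ratio, and the slightly different final analysis-set
#' size — both published figures are retained), total diagnostic codes,
#' and per-year uncoded-visit counts.
#'
#' @return A named list of counts.
#' @export
reference_headline <- function() {
  list(
    total_visits = 3555799,
    coded_visits = 2824371,
    analysis_set_visits = 2824185,
    total_codes = 3921974,
    visits_2019 = 1421779,
    uncoded_2019 = 262460,
    visits_2020 = 1402406,
    uncoded_2020 = 315541
  )
}
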