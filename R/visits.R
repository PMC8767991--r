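default_recodes <- function() {
  list(
    modality = c(
      f2f = "face_to_face", face_to_face = "face_to_face",
      presencial = "face_to_face",
      tm = "telemedicine", telemedicine = "telemedicine",
      nf2f = "telemedicine", telematic = "telemedicine"
    ),
    specialty = c(
      gp = "general_medicine", gm = "general_medicine",
      general_medicine = "general_medicine",
      nur = "nursing", nursing = "nursing",
      ped = "pediatrics", pediatrics = "pediatrics",
      other = "other"
    ),
    sex = c(
      m = "male", male = "male",
      f = "female", female = "female",
      u = "unknown", unknown = "unknown"
    )
  )
}

#' Visit modality, specialty and sex levels
#'
#' Canonical category levels used throughout the package.
#' @name visit_levels
#' @keywords internal
NULL

modality_levels <- c("face_to_face", "telemedicine")
specialty_levels <- c("general_medicine", "nursing", "pediatrics", "other")
sex_levels <- c("male", "female", "unknown")

recode_level <- function(x, map) {
  y <- unname(map[tolower(trimws(x))])
  bad <- is.na(y) & !is.na(x)
  list(value = y, bad = bad)
}

#' Read visit-level records from CSV
#'
#' Reads one-row-per-visit records with zero or more attached ICD-10 codes.
#' The expected columns are `visit_id`, `patient_id`, `date` (ISO 8601),
#' `modality`, `specialty`, `sex`, `age` and `codes` (delimiter-separated
#' list, empty for uncoded visits); `col_map` renames file columns onto this
#' schema. Modality/specialty/sex encodings such as `"F2F"`, `"GP"`, `"F"`
#' are recoded onto the canonical levels.
#'
#' Rows failing validation (unparseable date, negative age, malformed code,
#' unknown category level, duplicate visit id) are either skipped with a
#' message reporting the count (`on_error = "skip"`, default) or abort the
#' read (`on_error = "fail"`).
#'
#' @param path CSV file (UTF-8, header row).
#' @param col_map Optional named character vector mapping schema names to
#'   file column names, e.g. `c(visit_id = "id_visita")`.
#' @param code_delim Delimiter between codes within the `codes` field
#'   (default `";"`).
#' @param on_error `"skip"` or `"fail"`.
#' @return A tibble of validated visits with a list-column `codes` of
#'   normalized category-bearing codes; the number of skipped rows is
#'   attached as attribute `n_skipped`.
#' @export
read_visits <- function(path, col_map = NULL, code_delim = ";",
                        on_error = c("skip", "fail")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) {
    abort(sprintf("Visit file not found: %s", path))
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  needed <- c(
    "visit_id", "patient_id", "date", "modality", "specialty",
    "sex", "age", "codes"
  )
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        abort(sprintf("Mapped column \"%s\" not in file.", col_map[[std]]))
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Visit file is missing mandatory column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  validate_visits(raw[needed], code_delim = code_delim, on_error = on_error)
}

validate_visits <- function(raw, code_delim = ";", on_error = "skip") {
  maps <- default_recodes()
  date <- as.Date(suppressWarnings(readr::parse_date(raw$date,
    format = "%Y-%m-%d", na = c("", "NA")
  )))
  age <- suppressWarnings(as.integer(raw$age))
  modality <- recode_level(raw$modality, maps$modality)
  specialty <- recode_level(raw$specialty, maps$specialty)
  sex <- recode_level(raw$sex, maps$sex)

  codes_field <- ifelse(is.na(raw$codes), "", raw$codes)
  split_codes <- strsplit(codes_field, code_delim, fixed = TRUE)
  split_codes <- lapply(split_codes, function(cs) {
    cs <- trimws(cs)
    cs[nzchar(cs)]
  })
  code_ok <- vapply(split_codes, function(cs) {
    if (length(cs) == 0) {
      return(TRUE)
    }
    !inherits(try(icd_normalize(cs), silent = TRUE), "try-error")
  }, logical(1))

  bad <- is.na(date) | is.na(age) | age < 0 |
    modality$bad | is.na(modality$value) |
    specialty$bad | is.na(specialty$value) |
    sex$bad | is.na(sex$value) |
    is.na(raw$visit_id) | duplicated(raw$visit_id) | !code_ok
  if (any(bad) && on_error == "fail") {
    abort(sprintf(
      "%d visit row(s) failed validation (first offending visit_id: %s).",
      sum(bad), raw$visit_id[which(bad)[1]]
    ))
  }
  if (any(bad)) {
    inform(sprintf("Skipped %d malformed visit row(s).", sum(bad)))
  }
  keep <- !bad
  out <- tibble::tibble(
    visit_id = raw$visit_id[keep],
    patient_id = raw$patient_id[keep],
    date = date[keep],
    modality = factor(modality$value[keep], levels = modality_levels),
    specialty = factor(specialty$value[keep], levels = specialty_levels),
    sex = factor(sex$value[keep], levels = sex_levels),
    age = age[keep],
    codes = lapply(split_codes[keep], function(cs) {
      if (length(cs) == 0) character(0) else icd_normalize(cs)$normalized
    })
  )
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write visit records to CSV
#'
#' Inverse of [read_visits()]: serializes a visit tibble (list-column
#' `codes` joined on `code_delim`) so that reading the file back yields the
#' same records.
#'
#' @param visits A visit tibble.
#' @param path Output CSV path.
#' @param code_delim Delimiter between codes (default `";"`).
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path, code_delim = ";") {
  flat <- dplyr::mutate(
    visits,
    codes = vapply(.data$codes, paste, character(1), collapse = code_delim),
    date = format(.data$date, "%Y-%m-%d")
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Keep only coded visits
#'
#' Diagnosis coding is not mandatory in primary-care records, so analyses
#' of the diagnostic mix are restricted to visits carrying at least one
#' ICD-10 code. This filter is idempotent.
#'
#' @param visits A visit tibble.
#' @return The subset of `visits` with one or more codes.
#' @seealso [coding_summary()] for the per-period fraction of uncoded
#'   visits that this filter drops.
#' @export
filter_coded <- function(visits) {
  visits[lengths(visits$codes) > 0, ]
}

#' Per-period coding completeness
#'
#' Reports, for each date partition (or overall), how many visits carry at
#' least one diagnostic code and the percentage that do not — the
#' missing-coding fraction the coded-visit filter removes.
#'
#' @param visits A visit tibble.
#' @param partitions Optional [partition_spec()]; `NULL` summarises all
#'   visits as one period.
#' @return A tibble with columns `period`, `n_visits`, `n_coded`,
#'   `n_uncoded`, `missing_pct`, `coded_pct`.
#' @export
coding_summary <- function(visits, partitions = NULL) {
  period <- if (is.null(partitions)) {
    rep("all", nrow(visits))
  } else {
    assign_partition(visits$date, partitions)
  }
  df <- tibble::tibble(period = period, coded = lengths(visits$codes) > 0)
  df <- df[!is.na(df$period), ]
  lv <- if (is.null(partitions)) "all" else partitions$name
  df$period <- factor(df$period, levels = lv)
  out <- df |>
    dplyr::group_by(.data$period, .drop = FALSE) |>
    dplyr::summarise(
      n_visits = dplyr::n(),
      n_coded = sum(.data$coded),
      n_uncoded = sum(!.data$coded),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      missing_pct = 100 * .data$n_uncoded / .data$n_visits,
      coded_pct = 100 * .data$n_coded / .data$n_visits,
      period = as.character(.data$period)
    )
  out
}

#' Age-group bins for visit stratification
#'
#' The six age groups partition the non-negative integers with no gaps or
#' overlaps: early childhood 0-5, childhood 6-11, adolescence 12-18, youth
#' 19-26, adulthood 27-59, older adult 60 and over.
#'
#' @return A tibble with columns `name`, `lower`, `upper` (inclusive bounds;
#'   `Inf` for the open-ended last bin).
#' @export
age_group_bounds <- function() {
  tibble::tibble(
    name = c(
      "early_childhood", "childhood", "adolescence", "youth",
      "adulthood", "older_adult"
    ),
    lower = c(0, 6, 12, 19, 27, 60),
    upper = c(5, 11, 18, 26, 59, Inf)
  )
}

#' Assign ages to age groups
#'
#' @param age Integer vector of ages in years (must be non-negative).
#' @return A factor with the six [age_group_bounds()] levels.
#' @examples
#' assign_age_group(c(4, 30, 60))
#' @export
assign_age_group <- function(age) {
  if (any(is.na(age)) || any(age < 0)) {
    abort("Ages must be non-negative and non-missing.")
  }
  b <- age_group_bounds()
  idx <- findInterval(age, b$lower)
  factor(b$name[idx], levels = b$name)
}

#' Cohort descriptors by period
#'
#' Computes the standard visit-cohort description for each date partition:
#' distinct patients, total visits, visit counts and within-period shares by
#' modality, specialty, age group and sex, total diagnostic codes, mean and
#' SD of codes per visit, and mean and SD of age. When there are exactly
#' two partitions a `diff_pct` column gives the between-period relative
#' change, `100 * (late - early) / early`, for every descriptor.
#'
#' Empty partitions yield `NA` descriptors (flagged with a message), never
#' zeros, so that an accidentally empty period cannot masquerade as a real
#' collapse in activity.
#'
#' @param visits A visit tibble (coded and uncoded visits both count here).
#' @param partitions A [partition_spec()].
#' @return A tibble of class `cohort_summary`, one row per (descriptor,
#'   period): columns `family`, `characteristic`, `statistic`
#'   (`"count"`/`"mean"`), `period`, `value`, `pct` (within-family share),
#'   `sd`, and `diff_pct` (repeated across the descriptor's rows when two
#'   partitions are given).
#' @export
cohort_summary <- function(visits, partitions) {
  stopifnot(inherits(partitions, "partition_spec"))
  visits <- dplyr::mutate(
    visits,
    period = factor(assign_partition(.data$date, partitions),
      levels = partitions$name
    ),
    age_group = assign_age_group(.data$age),
    n_codes = lengths(.data$codes)
  )
  visits <- visits[!is.na(visits$period), ]

  empty <- setdiff(partitions$name, unique(as.character(visits$period)))
  if (length(empty) > 0) {
    inform(sprintf(
      "Empty partition(s) %s: descriptors reported as NA.",
      paste(empty, collapse = ", ")
    ))
  }

  count_family <- function(var, family) {
    visits |>
      dplyr::count(.data$period, .data[[var]], .drop = FALSE) |>
      dplyr::group_by(.data$period) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::transmute(
        family = family,
        characteristic = as.character(.data[[var]]),
        statistic = "count",
        period = as.character(.data$period),
        value = as.numeric(.data$n),
        pct = .data$pct,
        sd = NA_real_
      )
  }
  scalar_row <- function(family, characteristic, statistic, vals) {
    tibble::tibble(
      family = family, characteristic = characteristic,
      statistic = statistic, period = partitions$name,
      value = vals$value, pct = NA_real_, sd = vals$sd
    )
  }
  per_period <- function(f) {
    v <- vapply(partitions$name, function(p) {
      sub <- visits[as.character(visits$period) == p, ]
      if (nrow(sub) == 0) NA_real_ else f(sub)
    }, numeric(1))
    unname(v)
  }

  rows <- dplyr::bind_rows(
    scalar_row("patients", "total_patients", "count", list(
      value = per_period(function(s) dplyr::n_distinct(s$patient_id)),
      sd = rep(NA_real_, nrow(partitions))
    )),
    scalar_row("visits", "total_visits", "count", list(
      value = per_period(nrow), sd = rep(NA_real_, nrow(partitions))
    )),
    count_family("modality", "modality"),
    count_family("specialty", "specialty"),
    count_family("age_group", "age_group"),
    count_family("sex", "sex"),
    scalar_row("codes", "total_codes", "count", list(
      value = per_period(function(s) sum(s$n_codes)),
      sd = rep(NA_real_, nrow(partitions))
    )),
    scalar_row("codes", "codes_per_visit", "mean", list(
      value = per_period(function(s) mean(s$n_codes)),
      sd = per_period(function(s) stats::sd(s$n_codes))
    )),
    scalar_row("age", "age", "mean", list(
      value = per_period(function(s) mean(s$age)),
      sd = per_period(function(s) stats::sd(s$age))
    ))
  )
  # zero-visit periods: counts computed as 0 must be flagged NA instead
  if (length(empty) > 0) {
    rows$value[rows$period %in% empty] <- NA_real_
    rows$pct[rows$period %in% empty] <- NA_real_
  }
  if (nrow(partitions) == 2) {
    p <- partitions$name
    rows <- rows |>
      dplyr::group_by(.data$family, .data$characteristic, .data$statistic) |>
      dplyr::mutate(
        diff_pct = 100 *
          (.data$value[match(p[2], .data$period)] -
            .data$value[match(p[1], .data$period)]) /
          .data$value[match(p[1], .data$period)]
      ) |>
      dplyr::ungroup()
  }
  structure(rows,
    class = c("cohort_summary", class(tibble::tibble())),
    periods = partitions$name
  )
}
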