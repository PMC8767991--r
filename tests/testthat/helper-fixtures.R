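# in-code fixture builders shared across test files

make_visits <- function(codes,
                        date = as.Date("2019-06-15"),
                        modality = "face_to_face",
                        specialty = "general_medicine",
                        sex = "female",
                        age = 40,
                        patient_id = NULL) {
  n <- length(codes)
  tibble::tibble(
    visit_id = sprintf("v%04d", seq_len(n)),
    patient_id = patient_id %||% sprintf("p%04d", seq_len(n)),
    date = rep_len(as.Date(date), n),
    modality = factor(rep_len(modality, n), levels = c("face_to_face", "telemedicine")),
    specialty = factor(rep_len(specialty, n),
      levels = c("general_medicine", "nursing", "pediatrics", "other")
    ),
    sex = factor(rep_len(sex, n), levels = c("male", "female", "unknown")),
    age = as.integer(rep_len(age, n)),
    codes = lapply(codes, as.character)
  )
}

`%||%` <- rlang::`%||%`

two_years <- year_partitions(c(2019, 2020))

# random small cohort drawn from a fixed category inventory, for
# property-style tests (not the synthetic generator: plain draws)
random_visits <- function(n, seed) {
  set.seed(seed)
  cats <- c(
    "I10", "I21", "E11", "E66", "Z20", "Z59", "J06", "J45", "M54",
    "T14", "U07", "C21", "B34", "R05", "F41", "E95"
  )
  make_visits(
    codes = lapply(seq_len(n), function(i) {
      sample(cats, stats::rpois(1, 1.4), replace = TRUE)
    }),
    date = sample(
      seq(as.Date("2019-01-01"), as.Date("2020-12-31"), by = "day"),
      n,
      replace = TRUE
    ),
    modality = sample(c("face_to_face", "telemedicine"), n, replace = TRUE),
    specialty = sample(c("general_medicine", "nursing", "pediatrics"), n,
      replace = TRUE
    ),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = sample(0:95, n, replace = TRUE)
  )
}

# naive per-record recount: the independent oracle for build_matrix
naive_matrix <- function(visits, level, partitions, hierarchy = icd_hierarchy()) {
  out <- list()
  for (i in seq_len(nrow(visits))) {
    p <- NA_character_
    for (j in seq_len(nrow(partitions))) {
      if (visits$date[i] >= partitions$start[j] &&
        visits$date[i] < partitions$end[j]) {
        p <- partitions$name[j]
      }
    }
    if (is.na(p)) next
    for (code in visits$codes[[i]]) {
      g <- suppressMessages(icd_assign_group(code, level, hierarchy))
      key <- paste(p, g, sep = "\r")
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(period = character(), group = character(), n = integer()))
  }
  parts <- strsplit(names(out), "\r", fixed = TRUE)
  tibble::tibble(
    period = vapply(parts, `[[`, "", 1),
    group = vapply(parts, `[[`, "", 2),
    n = as.integer(unlist(out))
  ) |> dplyr::arrange(period, group)
}
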