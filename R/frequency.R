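new_freq_matrix <- function(counts, level, partitions, stratum = NULL,
                            n_remainder = 0L) {
  structure(
    counts,
    class = c("freq_matrix", class(tibble::tibble())),
    level = level,
    periods = partitions,
    stratum = stratum,
    n_remainder = n_remainder
  )
}

#' Stratum filters for visit subsets
#'
#' Builds a filter restricting the visits entering a frequency matrix to a
#' subset defined by modality, specialty, age group and/or sex (e.g. only
#' telemedicine visits). An empty filter keeps all visits.
#'
#' @param modality,specialty,age_group,sex Optional vectors of allowed
#'   levels.
#' @return A named list of class `stratum_filter`.
#' @examples
#' stratum_filter(modality = "face_to_face")
#' @export
stratum_filter <- function(modality = NULL, specialty = NULL,
                           age_group = NULL, sex = NULL) {
  check <- function(x, allowed, what) {
    if (!is.null(x) && !all(x %in% allowed)) {
      abort(sprintf(
        "Unknown %s level(s): %s", what,
        paste(setdiff(x, allowed), collapse = ", ")
      ))
    }
    x
  }
  out <- list(
    modality = check(modality, modality_levels, "modality"),
    specialty = check(specialty, specialty_levels, "specialty"),
    age_group = check(age_group, age_group_bounds()$name, "age group"),
    sex = check(sex, sex_levels, "sex")
  )
  structure(out[!vapply(out, is.null, logical(1))], class = "stratum_filter")
}

apply_stratum <- function(visits, stratum) {
  if (is.null(stratum) || length(stratum) == 0) {
    return(visits)
  }
  if ("age_group" %in% names(stratum)) {
    visits <- visits[as.character(assign_age_group(visits$age)) %in%
      stratum$age_group, ]
  }
  for (v in intersect(names(stratum), c("modality", "specialty", "sex"))) {
    visits <- visits[as.character(visits[[v]]) %in% stratum[[v]], ]
  }
  visits
}

#' Build a period-by-code-group term-frequency matrix
#'
#' Counts diagnostic-code occurrences per date partition and code grouping
#' at one aggregation level (1 chapter, 2 block, 3 category). A visit with
#' *k* codes contributes *k* occurrences — the cells count codes, not
#' visits — and duplicate identical codes on one visit count separately
#' unless `dedupe = TRUE`. Visits dated outside every partition are
#' excluded and their number recorded in the `n_remainder` attribute,
#' never silently absorbed.
#'
#' @param visits A visit tibble (typically after [filter_coded()]).
#' @param level Aggregation level 1, 2 or 3.
#' @param partitions A [partition_spec()].
#' @param stratum Optional [stratum_filter()].
#' @param hierarchy An [icd_hierarchy()].
#' @param dedupe Drop duplicate identical codes within a visit before
#'   counting (default `FALSE`: term-frequency semantics).
#' @param unmapped Passed to [icd_assign_group()].
#' @return A `freq_matrix`: a long tibble with columns `period`, `group`,
#'   `n` (zero-filled over all period-group combinations observed), with
#'   the level, partition names, stratum and out-of-partition visit count
#'   as attributes. Use [as.matrix()] for the wide periods-by-groups view.
#' @export
build_matrix <- function(visits, level, partitions,
                         stratum = NULL, hierarchy = icd_hierarchy(),
                         dedupe = FALSE, unmapped = "bucket") {
  stopifnot(inherits(partitions, "partition_spec"))
  visits <- apply_stratum(visits, stratum)
  period <- assign_partition(visits$date, partitions)
  n_remainder <- sum(is.na(period) & nrow(visits) > 0)
  visits <- visits[!is.na(period), ]
  period <- period[!is.na(period)]

  if (nrow(visits) == 0 || sum(lengths(visits$codes)) == 0) {
    warn("No code occurrences in any partition: returning an empty matrix.")
    counts <- tibble::tibble(
      period = character(), group = character(), n = integer()
    )
    return(new_freq_matrix(counts, level, partitions$name, stratum,
      n_remainder = n_remainder
    ))
  }

  codes <- visits$codes
  if (dedupe) codes <- lapply(codes, unique)
  k <- lengths(codes)
  long <- tibble::tibble(
    period = rep(period, k),
    group = icd_assign_group(unlist(codes), level,
      hierarchy = hierarchy, unmapped = unmapped
    )
  )
  counts <- long |>
    dplyr::count(.data$period, .data$group, name = "n") |>
    tidyr::complete(
      period = partitions$name,
      group = unique(long$group),
      fill = list(n = 0L)
    ) |>
    dplyr::arrange(.data$period, .data$group)
  new_freq_matrix(counts, level, partitions$name, stratum,
    n_remainder = n_remainder
  )
}

#' Build a frequency matrix directly from a table of per-period counts
#'
#' Published analyses often print the period-by-group counts themselves
#' (one row per code grouping, one count column per period). This
#' constructor turns such a table into a `freq_matrix` so the variation
#' metrics can be recomputed from printed inputs.
#'
#' @param df A data frame with a label column and one numeric count column
#'   per period.
#' @param label Name of the grouping-label column (default `"label"`).
#' @param periods Named character vector mapping period names to count
#'   columns, e.g. `c(Y2019 = "n_2019", Y2020 = "n_2020")`; defaults to all
#'   non-label columns, named by the column names.
#' @param level Aggregation level to record (default 1).
#' @return A `freq_matrix`.
#' @export
as_freq_matrix <- function(df, label = "label", periods = NULL, level = 1) {
  if (!label %in% names(df)) {
    abort(sprintf("Column \"%s\" not found.", label))
  }
  if (is.null(periods)) {
    cols <- setdiff(names(df), label)
    periods <- setNames(cols, cols)
  }
  if (!all(periods %in% names(df))) {
    abort("Period count column(s) not found in `df`.")
  }
  counts <- purrr::imap_dfr(periods, function(col, nm) {
    n <- df[[col]]
    if (!is_count(n)) {
      abort(sprintf("Column \"%s\" must hold non-negative counts.", col))
    }
    tibble::tibble(period = nm, group = df[[label]], n = as.integer(n))
  })
  new_freq_matrix(counts, level, names(periods))
}

#' @export
as.matrix.freq_matrix <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(x),
    names_from = "group", values_from = "n", values_fill = 0L
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$period
  m[attr(x, "periods"), , drop = FALSE]
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf(
    "<freq_matrix> level %d, %d period(s) x %d group(s)%s\n",
    attr(x, "level"), length(attr(x, "periods")),
    dplyr::n_distinct(x$group),
    if (!is.null(attr(x, "stratum"))) " (stratified)" else ""
  ))
  NextMethod()
}

#' Marginal totals and shares of a frequency matrix
#'
#' Sums each code grouping over all periods and expresses it as a
#' percentage of the grand total of code occurrences — the "Total, n (%)"
#' view of the matrix.
#'
#' @param matrix A `freq_matrix`.
#' @return A tibble with columns `group`, `total`, `share_pct`, sorted by
#'   descending total (ties broken by label).
#' @export
marginal_totals <- function(matrix) {
  stopifnot(inherits(matrix, "freq_matrix"))
  grand <- sum(matrix$n)
  tibble::as_tibble(matrix) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(share_pct = 100 * .data$total / grand) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$group)
}

#' Per-period totals of a frequency matrix
#'
#' @param matrix A `freq_matrix`.
#' @return A tibble with columns `period`, `total` in partition order.
#' @export
partition_totals <- function(matrix) {
  stopifnot(inherits(matrix, "freq_matrix"))
  tibble::as_tibble(matrix) |>
    dplyr::mutate(period = factor(.data$period, attr(matrix, "periods"))) |>
    dplyr::group_by(.data$period, .drop = FALSE) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(period = as.character(.data$period))
}

#' Top-k code groupings with cumulative shares
#'
#' Ranks groupings by total occurrences (descending, ties broken
#' lexicographically by label) and accumulates their share of the grand
#' total — the cumulative-frequency view of the most-used diagnostic
#' groupings.
#'
#' @param matrix A `freq_matrix`.
#' @param k Number of top groupings to keep; values beyond the number of
#'   groupings return all of them.
#' @return A tibble with columns `rank`, `group`, `total`, `share_pct`,
#'   `cum_share_pct` (monotone nondecreasing, at most 100).
#' @export
top_k <- function(matrix, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("`k` must be a single integer >= 1.")
  }
  marginal_totals(matrix) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      cum_share_pct = cumsum(.data$share_pct)
    ) |>
    dplyr::slice_head(n = as.integer(k)) |>
    dplyr::select(
      "rank", "group", "total", "share_pct", "cum_share_pct"
    )
}
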