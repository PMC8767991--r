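#' Define named date partitions
#'
#' A partition spec is a set of named, pairwise-disjoint, closed-open date
#' intervals `[start, end)` used to aggregate visit-level records by date.
#' The shipped default for a two-year before/during comparison is
#' [year_partitions()].
#'
#' @param ... Named intervals, each a length-2 vector coercible to `Date`
#'   (`c(start, end)`), end exclusive.
#' @return A tibble of class `partition_spec` with columns `name`, `start`,
#'   `end`.
#' @examples
#' partition_spec(
#'   Y2019 = c("2019-01-01", "2020-01-01"),
#'   Y2020 = c("2020-01-01", "2021-01-01")
#' )
#' @export
partition_spec <- function(...) {
  intervals <- list(...)
  if (length(intervals) == 0) {
    abort("A partition spec needs at least one named interval.")
  }
  nms <- names(intervals)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    abort("Partition intervals must have unique non-empty names.")
  }
  spec <- purrr::map2_dfr(intervals, nms, function(iv, nm) {
    iv <- as.Date(iv)
    if (length(iv) != 2 || anyNA(iv)) {
      abort(sprintf("Partition \"%s\" must be two parseable dates.", nm))
    }
    if (iv[2] <= iv[1]) {
      abort(sprintf("Partition \"%s\" has end <= start.", nm))
    }
    tibble::tibble(name = nm, start = iv[1], end = iv[2])
  })
  ord <- order(spec$start)
  sorted <- spec[ord, ]
  if (nrow(sorted) > 1 &&
    any(sorted$start[-1] < sorted$end[-nrow(sorted)])) {
    abort("Partition intervals overlap; they must be pairwise disjoint.")
  }
  structure(spec, class = c("partition_spec", class(tibble::tibble())))
}

#' @rdname partition_spec
#' @param years Integer vector of calendar years, one partition per year
#'   named `Y<year>`.
#' @export
year_partitions <- function(years = c(2019, 2020)) {
  iv <- lapply(years, function(y) {
    c(sprintf("%d-01-01", y), sprintf("%d-01-01", y + 1))
  })
  names(iv) <- sprintf("Y%d", years)
  do.call(partition_spec, iv)
}

#' Assign dates to partitions
#'
#' @param dates A `Date` vector.
#' @param partitions A [partition_spec()].
#' @return Character vector of partition names, `NA` for dates outside all
#'   intervals.
#' @export
assign_partition <- function(dates, partitions) {
  stopifnot(inherits(partitions, "partition_spec"))
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  for (i in seq_len(nrow(partitions))) {
    in_i <- !is.na(dates) &
      dates >= partitions$start[i] & dates < partitions$end[i]
    out[in_i] <- partitions$name[i]
  }
  out
}
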