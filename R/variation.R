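#' Interannual variation percentage
#'
#' Relative change of a count between two periods,
#' `100 * (n_late - n_early) / n_early`. With a zero baseline the change is
#' undefined and reported as `NA` (never 0 or infinity); such groups still
#' contribute their absolute change to the variation-index denominator.
#'
#' @param n_early,n_late Non-negative counts (vectorized).
#' @return Numeric vector of percentages, `NA` where `n_early` is zero.
#' @examples
#' interannual_variation(186604, 296764) # +59.03
#' @export
interannual_variation <- function(n_early, n_late) {
  ok <- function(x) is.numeric(x) && !anyNA(x) && all(x >= 0)
  if (!ok(n_early) || !ok(n_late)) {
    abort("`n_early` and `n_late` must be non-negative counts.")
  }
  out <- 100 * (n_late - n_early) / n_early
  out[n_early == 0] <- NA_real_
  out
}

#' Variation index
#'
#' Normalizes each group's absolute count change by the summed absolute
#' changes of all groups in scope: `VI_c = |delta_c| / sum |delta_c'|`. The
#' index weights each group's contribution to the total disruption between
#' the two periods and sums to 1. When every change is zero the index is
#' undefined and all values are `NA` (never 0/0).
#'
#' @param deltas Numeric vector of count changes (`n_late - n_early`), one
#'   per group in the table being reported.
#' @return Numeric vector of indices in `[0, 1]` summing to 1, or all `NA`
#'   if all deltas are zero.
#' @examples
#' variation_index(c(10, -10))
#' @export
variation_index <- function(deltas) {
  if (length(deltas) == 0) {
    abort("`deltas` must contain at least one group.")
  }
  if (any(is.na(deltas))) {
    abort("`deltas` must not contain missing values.")
  }
  denom <- sum(abs(deltas))
  if (denom == 0) {
    warn("All deltas are zero: variation index is undefined.")
    return(rep(NA_real_, length(deltas)))
  }
  abs(deltas) / denom
}

#' Variation table from a two-period frequency matrix
#'
#' The central report of the package: for every code grouping in a
#' two-period matrix, the per-period counts and within-period shares, the
#' absolute change, the interannual variation percentage, and the variation
#' index computed over exactly the matrix's groupings (i.e. within the
#' stratum and aggregation level of the matrix).
#'
#' @param matrix A `freq_matrix` with exactly two periods (the first in
#'   partition order is the baseline).
#' @param sort `"by_total"` (descending total, the usual full-table view) or
#'   `"by_index"` (descending variation index, the top-disruption view).
#'   Ties are broken lexicographically by label.
#' @return A tibble of class `variation_table` with columns `group`,
#'   `n_early`, `n_late`, `total`, `share_pct`, `share_early_pct`,
#'   `share_late_pct`, `delta`, `iav_pct`, `vi`. Periods, level and stratum
#'   are carried as attributes.
#' @examples
#' ref <- reference_table("chapters")
#' fm <- as_freq_matrix(ref, periods = c(Y2019 = "n_2019", Y2020 = "n_2020"))
#' variation_table(fm, sort = "by_index")
#' @export
variation_table <- function(matrix, sort = c("by_total", "by_index")) {
  sort <- match.arg(sort)
  stopifnot(inherits(matrix, "freq_matrix"))
  periods <- attr(matrix, "periods")
  if (length(periods) != 2) {
    abort(sprintf(
      "A variation table needs exactly 2 periods; the matrix has %d.",
      length(periods)
    ))
  }
  wide <- tibble::as_tibble(matrix) |>
    tidyr::pivot_wider(
      names_from = "period", values_from = "n", values_fill = 0L
    )
  for (p in setdiff(periods, names(wide))) wide[[p]] <- 0L
  n_early <- wide[[periods[1]]]
  n_late <- wide[[periods[2]]]
  delta <- n_late - n_early
  out <- tibble::tibble(
    group = wide$group,
    n_early = n_early,
    n_late = n_late,
    total = n_early + n_late,
    share_pct = 100 * (n_early + n_late) / sum(n_early + n_late),
    share_early_pct = 100 * n_early / sum(n_early),
    share_late_pct = 100 * n_late / sum(n_late),
    delta = delta,
    iav_pct = interannual_variation(n_early, n_late),
    vi = if (nrow(wide) > 0) variation_index(delta) else numeric()
  )
  out <- switch(sort,
    by_total = dplyr::arrange(out, dplyr::desc(.data$total), .data$group),
    by_index = dplyr::arrange(out, dplyr::desc(.data$vi), .data$group)
  )
  structure(out,
    class = c("variation_table", class(tibble::tibble())),
    periods = periods,
    level = attr(matrix, "level"),
    stratum = attr(matrix, "stratum"),
    sort = sort
  )
}

#' Per-group counts and variation index for two-period scatter plots
#'
#' One row per code grouping with both period counts and the variation
#' index — the table underlying a before-vs-during log-log scatter, where
#' groups on the identity diagonal were used equally often in both periods.
#'
#' @param matrix A `freq_matrix` with exactly two periods.
#' @return A tibble with columns `group`, `n_early`, `n_late`, `vi`.
#' @export
scatter_table <- function(matrix) {
  stopifnot(inherits(matrix, "freq_matrix"))
  if (nrow(matrix) == 0) {
    return(tibble::tibble(
      group = character(), n_early = integer(), n_late = integer(),
      vi = numeric()
    ))
  }
  vt <- variation_table(matrix, sort = "by_total")
  dplyr::select(tibble::as_tibble(vt), "group", "n_early", "n_late", "vi")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variation table
#'
#' Returns the table as a plain tibble, optionally rounded the way printed
#' reports round: variation percentages and indices to 2 decimal places.
#'
#' @param x A `variation_table`.
#' @param rounded Round `iav_pct`, `vi` and shares to 2 dp (default
#'   `FALSE`: full precision).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy variation_table
#' @export
tidy.variation_table <- function(x, rounded = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (rounded) {
    out <- dplyr::mutate(out, dplyr::across(
      c("share_pct", "share_early_pct", "share_late_pct", "iav_pct", "vi"),
      round2
    ))
  }
  out
}

#' One-row summary of a variation table
#'
#' @param x A `variation_table`.
#' @param ... Unused.
#' @return A one-row tibble: number of groups, total code occurrences,
#'   summed absolute change, mean absolute interannual variation (over
#'   groups where it is defined), and the group with the largest variation
#'   index.
#' @method glance variation_table
#' @export
glance.variation_table <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x),
    total_codes = sum(x$total),
    sum_abs_delta = sum(abs(x$delta)),
    mean_abs_iav_pct = mean(abs(x$iav_pct), na.rm = TRUE),
    top_vi_group = if (nrow(x) > 0) x$group[which.max(x$vi)] else NA_character_,
    level = attr(x, "level") %||% NA_integer_
  )
}

#' @export
print.variation_table <- function(x, ...) {
  p <- attr(x, "periods")
  cat(sprintf(
    "<variation_table> %s vs %s, level %s, %d group(s)\n",
    p[1], p[2], attr(x, "level") %||% "?", nrow(x)
  ))
  NextMethod()
}
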