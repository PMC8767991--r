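#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: the visit source (an input
#' CSV *or* a synthetic-cohort simulation block — exactly one), the date
#' partitions, the aggregation levels and strata to compute, the top-k
#' cutoff, rounding for emitted tables, and the seed.
#'
#' @param input Path to a visit CSV (mutually exclusive with `simulate`).
#' @param simulate A [synthetic_config()], a list of arguments for one, or
#'   `TRUE` for the default configuration.
#' @param partitions A [partition_spec()] (variation tables need exactly
#'   two partitions).
#' @param levels Aggregation levels to compute (subset of 1:3).
#' @param strata Named list of stratum definitions; each element is `NULL`
#'   (all visits) or a list of [stratum_filter()] arguments.
#' @param top_k Rows kept in the ranked top-k views.
#' @param rounding Decimal places for derived columns in emitted tables.
#' @param format `"tsv"` or `"csv"`.
#' @param seed Integer seed used for simulation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       partitions = year_partitions(c(2019, 2020)),
                       levels = c(1, 2, 3),
                       strata = list(
                         all = NULL,
                         face_to_face = list(modality = "face_to_face"),
                         telemedicine = list(modality = "telemedicine")
                       ),
                       top_k = 21, rounding = 2,
                       format = c("tsv", "csv"), seed = 1) {
  format <- match.arg(format)
  if (is.null(input) == is.null(simulate)) {
    abort("Exactly one of `input` and `simulate` must be given.")
  }
  if (!is.null(input) && !file.exists(input)) {
    abort(sprintf("Input file not found: %s", input))
  }
  if (isTRUE(simulate)) simulate <- synthetic_config(periods = partitions)
  if (is.list(simulate) && !inherits(simulate, "synthetic_config")) {
    simulate <- do.call(
      synthetic_config, c(list(periods = partitions), simulate)
    )
  }
  stopifnot(inherits(partitions, "partition_spec"))
  if (!all(levels %in% 1:3)) abort("`levels` must be a subset of 1:3.")
  if (length(strata) == 0) strata <- list(all = NULL)
  if (is.null(names(strata)) || any(!nzchar(names(strata)))) {
    abort("`strata` must be a named list.")
  }
  structure(
    list(
      input = input, simulate = simulate, partitions = partitions,
      levels = sort(unique(levels)), strata = strata, top_k = top_k,
      rounding = rounding, format = format, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the [run_config()] arguments; `partitions` is a map of
#' name to `[start, end]` date pairs, and `simulate` is a map of
#' [synthetic_config()] arguments (or `true` for the defaults).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$partitions)) {
    args$partitions <- do.call(
      partition_spec, lapply(y$partitions, unlist)
    )
  }
  if (!is.null(y$simulate)) {
    args$simulate <- if (isTRUE(y$simulate)) TRUE else y$simulate
  }
  for (k in c(
    "input", "levels", "top_k", "rounding", "format", "seed"
  )) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$strata)) args$strata <- y$strata
  do.call(run_config, args)
}

config_hash <- function(config) {
  flat <- list(
    input = config$input,
    simulate = if (!is.null(config$simulate)) {
      unclass(config$simulate[c(
        "n_visits", "missingness", "patient_pool", "age_cap"
      )])
    },
    partitions = lapply(seq_len(nrow(config$partitions)), function(i) {
      c(
        config$partitions$name[i],
        format(config$partitions$start[i]), format(config$partitions$end[i])
      )
    }),
    levels = config$levels, strata = config$strata,
    top_k = config$top_k, rounding = config$rounding,
    format = config$format, seed = config$seed
  )
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(flat), tmp)
  unname(tools::md5sum(tmp))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage \"%s\" failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> coding filter -> cohort descriptors
#' -> term-frequency matrices -> variation tables, top-k views and scatter
#' tables for every configured level and stratum. Any stage error aborts
#' with a stage-named message. Reruns with an identical configuration are
#' fully reproducible.
#'
#' @param config A [run_config()].
#' @return A list of class `report_bundle`: `cohort`, `coding`, and
#'   per-level/stratum `variation`, `top`, `scatter` tables, plus a
#'   `manifest` recording package version, seed, configuration hash and
#'   per-table row counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  visits <- if (!is.null(config$input)) {
    with_stage("read", read_visits(config$input))
  } else {
    with_stage("simulate", generate_visits(config$simulate, seed = config$seed))
  }
  inform(sprintf("visits: %d record(s)", nrow(visits)))
  coding <- with_stage(
    "coding_summary", coding_summary(visits, config$partitions)
  )
  cohort <- with_stage(
    "cohort_summary", cohort_summary(visits, config$partitions)
  )
  coded <- with_stage("filter_coded", filter_coded(visits))
  inform(sprintf("coded visits: %d record(s)", nrow(coded)))

  two_periods <- nrow(config$partitions) == 2
  cells <- tidyr::expand_grid(
    level = config$levels, stratum = names(config$strata)
  )
  results <- purrr::pmap(cells, function(level, stratum) {
    sdef <- config$strata[[stratum]]
    sf <- if (is.null(sdef) || length(sdef) == 0) {
      NULL
    } else {
      do.call(stratum_filter, as.list(sdef))
    }
    fm <- with_stage(
      sprintf("build_matrix L%d/%s", level, stratum),
      build_matrix(coded, level, config$partitions, stratum = sf)
    )
    list(
      level = level, stratum = stratum,
      variation = if (two_periods) {
        with_stage(
          sprintf("variation L%d/%s", level, stratum),
          variation_table(fm, sort = "by_total")
        )
      },
      top = with_stage(
        sprintf("top_k L%d/%s", level, stratum), top_k(fm, config$top_k)
      ),
      scatter = if (two_periods) scatter_table(fm)
    )
  })
  names(results) <- sprintf("L%d_%s", cells$level, cells$stratum)

  manifest <- list(
    package = "icdshift",
    version = as.character(utils::packageVersion("icdshift")),
    seed = config$seed,
    config_hash = config_hash(config),
    periods = config$partitions$name,
    n_visits = nrow(visits),
    n_coded_visits = nrow(coded),
    tables = lapply(results, function(r) {
      list(
        variation_rows = if (!is.null(r$variation)) nrow(r$variation),
        top_rows = nrow(r$top)
      )
    })
  )
  structure(
    list(
      cohort = cohort, coding = coding, results = results,
      manifest = manifest, config = config
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(
    "<report_bundle> %d visit(s), %d result table set(s), seed %d\n",
    x$manifest$n_visits, length(x$results), x$manifest$seed
  ))
  invisible(x)
}

round_cols <- function(df, cols, digits) {
  dplyr::mutate(df, dplyr::across(dplyr::any_of(cols), ~ round(.x, digits)))
}

#' Emit report tables to disk
#'
#' Writes every table of a [run_pipeline()] bundle as TSV or CSV with a
#' deterministic column order and row sort, derived columns rounded per the
#' configuration, undefined values rendered as the literal `NA` sentinel
#' (never 0), and a YAML manifest alongside. Re-emitting the same bundle
#' yields byte-identical files. If any write fails, partial outputs are
#' removed.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"csv"`; defaults to the bundle configuration.
#' @return Character vector of the files written, invisibly.
#' @export
emit_tables <- function(bundle, dir, format = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  format <- format %||% bundle$config$format
  if (!format %in% c("tsv", "csv")) abort("`format` must be tsv or csv.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  digits <- bundle$config$rounding
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  ext <- paste0(".", format)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ext))
    writer(df, path, na = "NA", progress = FALSE)
    written <<- c(written, path)
  }
  pct_cols <- c(
    "pct", "missing_pct", "coded_pct", "diff_pct", "share_pct",
    "share_early_pct", "share_late_pct", "iav_pct", "cum_share_pct",
    "vi", "value", "sd"
  )
  tryCatch(
    {
      emit(
        round_cols(tibble::as_tibble(bundle$cohort), pct_cols, digits),
        "cohort_summary"
      )
      emit(
        round_cols(bundle$coding, pct_cols, digits),
        "coding_summary"
      )
      for (nm in names(bundle$results)) {
        r <- bundle$results[[nm]]
        if (!is.null(r$variation)) {
          emit(
            tidy(r$variation) |> round_cols(pct_cols, digits),
            paste0("variation_", nm)
          )
        }
        emit(round_cols(r$top, pct_cols, digits), paste0("top_", nm))
        if (!is.null(r$scatter)) {
          emit(
            round_cols(r$scatter, c("vi"), digits),
            paste0("scatter_", nm)
          )
        }
      }
      manifest_path <- file.path(dir, "manifest.yaml")
      writeLines(yaml::as.yaml(bundle$manifest), manifest_path)
      written <- c(written, manifest_path)
    },
    error = function(e) {
      unlink(written)
      abort(sprintf(
        "Table emission failed (partial outputs removed): %s",
        conditionMessage(e)
      ))
    }
  )
  invisible(written)
}
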