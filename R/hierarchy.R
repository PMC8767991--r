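#' Normalize ICD-10 diagnostic codes
#'
#' Brings raw ICD-10 codes into canonical form: uppercase, with dots and
#' whitespace removed (`"e11.9"` becomes `"E119"`), and extracts the
#' three-character category stem (`"E11"`) that drives all hierarchical
#' grouping. Normalization is idempotent: normalizing an already-normalized
#' code returns it unchanged.
#'
#' A structurally valid code starts with a letter followed by at least two
#' alphanumeric characters (the category), with an optional alphanumeric
#' suffix of arbitrary length. Anything else is rejected.
#'
#' @param x Character vector of raw ICD-10 codes.
#' @return A tibble with one row per input code and columns `raw`,
#'   `normalized` and `category`.
#' @examples
#' icd_normalize(c("Z20", "e11.9", "I10"))
#' @export
icd_normalize <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(
      raw = character(), normalized = character(), category = character()
    ))
  }
  if (!is.character(x)) {
    abort("ICD-10 codes must be supplied as a character vector.")
  }
  bad_empty <- is.na(x) | !nzchar(trimws(x))
  if (any(bad_empty)) {
    abort(sprintf(
      "ICD-10 codes must be non-empty text (%d empty or missing value(s)).",
      sum(bad_empty)
    ))
  }
  normalized <- toupper(gsub("[.[:space:]]", "", x))
  ok <- grepl("^[A-Z][0-9A-Z]{2,}$", normalized)
  if (!all(ok)) {
    offenders <- unique(x[!ok])
    abort(sprintf(
      "Malformed ICD-10 code(s): %s. Expected a letter followed by at least two alphanumerics.",
      paste(sprintf('"%s"', head(offenders, 5)), collapse = ", ")
    ))
  }
  tibble::tibble(
    raw = x,
    normalized = normalized,
    category = substr(normalized, 1, 3)
  )
}

# positional ordering key for a 3-character category stem:
# leading letter, then characters 2-3 with digits ordered before letters
# ('A' > '9'), so e.g. O9A sorts after O99 and the printed range O00-O9A
# is a proper interval.
icd_key <- function(stem) {
  chars <- c(0:9, LETTERS)
  pos <- function(ch) match(ch, chars) - 1L
  l <- match(substr(stem, 1, 1), LETTERS) - 1L
  a <- pos(substr(stem, 2, 2))
  b <- pos(substr(stem, 3, 3))
  if (anyNA(l) || anyNA(a) || anyNA(b)) {
    abort(sprintf(
      "Invalid category stem(s): %s",
      paste(unique(stem[is.na(l) | is.na(a) | is.na(b)]), collapse = ", ")
    ))
  }
  l * 36L * 36L + a * 36L + b
}

# inverse of icd_key
icd_unkey <- function(key) {
  chars <- c(0:9, LETTERS)
  l <- key %/% (36L * 36L)
  r <- key %% (36L * 36L)
  paste0(LETTERS[l + 1L], chars[r %/% 36L + 1L], chars[r %% 36L + 1L])
}

#' Enumerate the category stems covered by an ICD-10 code range
#'
#' Expands a range such as `"Z20"`--`"Z29"` into the three-character
#' category stems it covers, under the positional ordering used throughout
#' the package (digits sort before letters in positions 2-3, so `"O9A"`
#' falls inside `"O00"`--`"O9A"`).
#'
#' @param start,end Three-character category stems bounding the range
#'   (inclusive).
#' @return Character vector of category stems in order.
#' @examples
#' icd_expand_range("J00", "J06")
#' @export
icd_expand_range <- function(start, end) {
  ks <- icd_key(start)
  ke <- icd_key(end)
  if (ke < ks) {
    abort(sprintf("Range start %s exceeds end %s.", start, end))
  }
  icd_unkey(seq.int(ks, ke))
}

validate_ranges <- function(ranges, what) {
  stopifnot(all(c("start", "end", "label") %in% names(ranges)))
  ranges <- dplyr::mutate(
    ranges,
    key_start = icd_key(.data$start),
    key_end = icd_key(.data$end)
  )
  bad <- ranges$key_end < ranges$key_start
  if (any(bad)) {
    abort(sprintf(
      "%s range(s) with start after end: %s",
      what, paste(ranges$label[bad], collapse = "; ")
    ))
  }
  ranges <- dplyr::arrange(ranges, .data$key_start)
  if (nrow(ranges) > 1) {
    overlap <- ranges$key_start[-1] <= ranges$key_end[-nrow(ranges)]
    if (any(overlap)) {
      i <- which(overlap)[1]
      abort(sprintf(
        "Overlapping %s ranges: \"%s\" and \"%s\".",
        tolower(what), ranges$label[i], ranges$label[i + 1]
      ))
    }
  }
  ranges
}

#' Load and validate an ICD-10 grouping hierarchy
#'
#' Returns the mapping from three-character category stems to the two
#' coarser aggregation levels used in diagnosis-mix analyses: chapters
#' (level 1, e.g. "Neoplasms (C00-D49)") and blocks (level 2, e.g.
#' "Hypertensive diseases (I10-I16)"). The package ships a default table
#' following the ICD-10-CM tabular layout: the 21 regular chapters plus the
#' special-purpose chapter U00-U85 (so that pandemic-era codes such as U07
#' roll up cleanly), and the public block structure nested within them.
#'
#' A user-supplied CSV with columns `level` (`"chapter"`/`"block"` or
#' `1`/`2`), `start`, `end`, `label` overrides the default after passing the
#' same validation: ranges well-ordered, chapters pairwise disjoint, blocks
#' pairwise disjoint and each contained in exactly one chapter.
#'
#' @param path Optional path to a hierarchy CSV. `NULL` loads the packaged
#'   default.
#' @param include_special Keep the special-purpose chapter U00-U85
#'   (default `TRUE`).
#' @return An object of class `icd_hierarchy`: a list with tibbles
#'   `chapters` and `blocks`, each with `start`, `end`, `label` and
#'   precomputed ordering keys.
#' @examples
#' h <- icd_hierarchy()
#' nrow(h$chapters)
#' @export
icd_hierarchy <- function(path = NULL, include_special = TRUE) {
  if (is.null(path)) {
    cache_key <- paste0("default_hierarchy_", include_special)
    if (!is.null(the[[cache_key]])) {
      return(the[[cache_key]])
    }
    path <- system.file("extdata", "icd10_hierarchy.csv",
      package = "icdshift", mustWork = TRUE
    )
    caching <- TRUE
  } else {
    caching <- FALSE
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("level", "start", "end", "label"), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Hierarchy file is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  raw$level <- as.character(raw$level)
  raw$level[raw$level == "1"] <- "chapter"
  raw$level[raw$level == "2"] <- "block"
  if (!all(raw$level %in% c("chapter", "block"))) {
    abort("Hierarchy `level` must be \"chapter\"/1 or \"block\"/2.")
  }
  chapters <- validate_ranges(raw[raw$level == "chapter", -1], "Chapter")
  blocks <- validate_ranges(raw[raw$level == "block", -1], "Block")
  if (!include_special) {
    chapters <- chapters[substr(chapters$start, 1, 1) != "U", ]
    blocks <- blocks[substr(blocks$start, 1, 1) != "U", ]
  }
  # each block must lie inside exactly one chapter
  ch_idx <- findInterval(blocks$key_start, chapters$key_start)
  contained <- ch_idx >= 1 &
    blocks$key_start >= chapters$key_start[pmax(ch_idx, 1)] &
    blocks$key_end <= chapters$key_end[pmax(ch_idx, 1)]
  if (!all(contained)) {
    abort(sprintf(
      "Block(s) not contained in a single chapter: %s",
      paste(blocks$label[!contained], collapse = "; ")
    ))
  }
  blocks$chapter_label <- chapters$label[ch_idx]
  h <- structure(
    list(chapters = chapters, blocks = blocks),
    class = "icd_hierarchy"
  )
  if (caching) the[[cache_key]] <- h
  h
}

#' @export
print.icd_hierarchy <- function(x, ...) {
  cat(sprintf(
    "<icd_hierarchy> %d chapters, %d blocks\n",
    nrow(x$chapters), nrow(x$blocks)
  ))
  invisible(x)
}

lookup_range <- function(keys, ranges) {
  idx <- findInterval(keys, ranges$key_start)
  hit <- idx >= 1 & keys <= ifelse(idx >= 1, ranges$key_end[pmax(idx, 1)], -1)
  out <- rep(NA_character_, length(keys))
  out[hit] <- ranges$label[idx[hit]]
  out
}

#' Assign ICD-10 codes to their grouping label at an aggregation level
#'
#' Maps each code to its chapter label (level 1), block label (level 2) or
#' three-character category stem (level 3). Dot-suffixed codes (`"E11.9"`)
#' are grouped by their category stem at every level. Codes whose stem falls
#' outside all ranges are, by default, routed to an explicit `"UNMAPPED"`
#' bucket (with a message giving the count) so that totals remain
#' conserved; set `unmapped = "error"` to reject them instead.
#'
#' @param codes Character vector of ICD-10 codes (raw or normalized).
#' @param level Aggregation level: 1 (chapter), 2 (block) or 3 (category).
#' @param hierarchy An [icd_hierarchy()] object.
#' @param unmapped `"bucket"` (default) or `"error"`.
#' @return Character vector of grouping labels, same length as `codes`.
#' @examples
#' icd_assign_group(c("I10", "Z20"), level = 2)
#' @export
icd_assign_group <- function(codes, level, hierarchy = icd_hierarchy(),
                             unmapped = c("bucket", "error")) {
  unmapped <- match.arg(unmapped)
  if (!level %in% 1:3) {
    abort("`level` must be 1 (chapter), 2 (block) or 3 (category).")
  }
  stems <- icd_normalize(codes)$category
  if (level == 3) {
    return(stems)
  }
  ranges <- if (level == 1) hierarchy$chapters else hierarchy$blocks
  labels <- lookup_range(icd_key(stems), ranges)
  n_miss <- sum(is.na(labels))
  if (n_miss > 0) {
    if (unmapped == "error") {
      abort(sprintf(
        "%d code(s) fall outside every level-%d range, e.g. %s.",
        n_miss, level, paste(head(unique(stems[is.na(labels)]), 5), collapse = ", ")
      ))
    }
    inform(sprintf(
      "%d code occurrence(s) outside every level-%d range routed to \"UNMAPPED\".",
      n_miss, level
    ))
    labels[is.na(labels)] <- "UNMAPPED"
  }
  labels
}
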