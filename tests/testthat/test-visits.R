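write_visit_csv <- function(lines) {
  tmp <- withr::local_tempfile(
    fileext = ".csv",
    .local_envir = parent.frame()
  )
  writeLines(c("visit_id,patient_id,date,modality,specialty,sex,age,codes", lines), tmp)
  tmp
}

test_that("read_visits parses rows, splits codes and recodes levels", {
  path <- write_visit_csv(c(
    "v1,p1,2019-03-04,F2F,GP,F,54,I10;E11",
    "v2,p1,2020-05-01,TM,NUR,M,60,",
    "v3,p2,2019-07-09,face_to_face,PED,F,4,Z20"
  ))
  v <- read_visits(path)
  expect_equal(nrow(v), 3)
  expect_equal(v$codes[[1]], c("I10", "E11"))
  expect_length(v$codes[[2]], 0)
  expect_equal(as.character(v$modality), c("face_to_face", "telemedicine", "face_to_face"))
  expect_equal(as.character(v$specialty[2]), "nursing")
  expect_s3_class(v$date, "Date")
  expect_equal(attr(v, "n_skipped"), 0)
})

test_that("malformed rows are skipped with a count, or fail fast", {
  path <- write_visit_csv(c(
    "v1,p1,2019-03-04,F2F,GP,F,54,I10",
    "v2,p1,04/03/2019,F2F,GP,F,54,I10", # non-ISO date
    "v3,p1,2019-03-04,F2F,GP,F,-2,I10", # negative age
    "v4,p1,2019-03-04,F2F,GP,F,54,1X0" # malformed code
  ))
  expect_message(v <- read_visits(path), "Skipped 3")
  expect_equal(v$visit_id, "v1")
  expect_error(read_visits(path, on_error = "fail"), "v2")
})

test_that("missing mandatory columns are a fatal error, col_map renames", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,patient_id,date,modality,specialty,sex,age,codes",
    "v1,p1,2019-03-04,F2F,GP,F,54,I10"), tmp)
  expect_error(read_visits(tmp), "visit_id")
  v <- read_visits(tmp, col_map = c(visit_id = "id"))
  expect_equal(v$visit_id, "v1")
  expect_error(read_visits(tempfile()), "not found")
})

test_that("visit round trip through write_visits preserves records", {
  v <- random_visits(60, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_visits(v, tmp)
  v2 <- read_visits(tmp)
  expect_equal(
    dplyr::mutate(v2, codes = unname(codes)),
    dplyr::mutate(v, codes = unname(codes)),
    ignore_attr = TRUE
  )
})

test_that("filter_coded keeps exactly the coded visits and is idempotent", {
  v <- make_visits(list(c("I10"), character(0), c("E11", "Z20")))
  kept <- filter_coded(v)
  expect_equal(kept$visit_id, c("v0001", "v0003"))
  expect_equal(filter_coded(kept), kept)
  expect_equal(nrow(kept) + sum(lengths(v$codes) == 0), nrow(v))
})

test_that("coding_summary reports per-period missing fractions", {
  v <- make_visits(
    codes = list("I10", character(0), "E11", "Z20", character(0), "J06"),
    date = as.Date(c(
      "2019-02-01", "2019-06-01", "2019-09-01",
      "2020-02-01", "2020-06-01", "2020-09-01"
    ))
  )
  cs <- coding_summary(v, two_years)
  expect_equal(cs$period, c("Y2019", "Y2020"))
  expect_equal(cs$missing_pct, c(100 / 3, 100 / 3))
  all_coded <- coding_summary(filter_coded(v))
  expect_equal(all_coded$missing_pct, 0)
})

test_that("age groups are total, disjoint and match the published bins", {
  expect_equal(as.character(assign_age_group(4)), "early_childhood")
  expect_equal(as.character(assign_age_group(30)), "adulthood")
  expect_equal(as.character(assign_age_group(60)), "older_adult")
  # every age maps to exactly one bin, with the published boundaries
  ages <- 0:120
  groups <- assign_age_group(ages)
  expect_false(anyNA(groups))
  expect_equal(
    as.vector(table(groups)[age_group_bounds()$name]),
    c(6, 6, 7, 8, 33, 61)
  )
  expect_error(assign_age_group(-1), "non-negative")
})

test_that("cohort_summary reproduces counts, shares and difference %", {
  v <- dplyr::bind_rows(
    make_visits(list("I10", c("E11", "E66"), character(0)),
      date = "2019-05-01", modality = "face_to_face", sex = "female", age = 70
    ),
    make_visits(list("Z20"),
      date = "2020-05-01", modality = "telemedicine", sex = "male", age = 30
    )
  )
  v$visit_id <- sprintf("v%d", seq_len(nrow(v)))
  cs <- cohort_summary(v, two_years)
  get <- function(ch, p, col = "value") {
    cs[[col]][cs$characteristic == ch & cs$period == p]
  }
  expect_equal(get("total_visits", "Y2019"), 3)
  expect_equal(get("total_visits", "Y2020"), 1)
  expect_equal(get("total_visits", "Y2019", "diff_pct"), 100 * (1 - 3) / 3)
  expect_equal(get("face_to_face", "Y2019", "pct"), 100)
  expect_equal(get("total_codes", "Y2019"), 3)
  expect_equal(get("codes_per_visit", "Y2019"), 1)
  expect_equal(get("age", "Y2020"), 30)
  # shares within each categorical family sum to 100
  fam <- dplyr::filter(cs, statistic == "count", !is.na(pct))
  sums <- tapply(fam$pct, list(fam$family, fam$period), sum)
  expect_true(all(abs(sums - 100) < 0.1))
})

test_that("a single-visit dataset yields 100% shares", {
  v <- make_visits(list("I10"), date = "2019-05-01")
  cs <- cohort_summary(v, two_years)
  shares <- cs$pct[cs$period == "Y2019" & !is.na(cs$pct) & cs$pct > 0]
  expect_true(all(shares == 100))
})

test_that("empty partitions are flagged NA, not zero", {
  v <- make_visits(list("I10"), date = "2019-05-01")
  expect_message(cs <- cohort_summary(v, two_years), "Y2020")
  expect_true(all(is.na(cs$value[cs$period == "Y2020"])))
})
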