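ref_matrix <- function() {
  as_freq_matrix(
    reference_table("chapters"),
    periods = c(Y2019 = "n_2019", Y2020 = "n_2020")
  )
}

test_that("cells count code occurrences, not visits", {
  v <- make_visits(list(c("I10", "E11")), date = "2019-05-01")
  fm <- build_matrix(v, 2, two_years)
  counts <- dplyr::filter(tibble::as_tibble(fm), n > 0)
  expect_equal(sort(counts$group), sort(c(
    icd_assign_group("I10", 2), icd_assign_group("E11", 2)
  )))
  expect_equal(counts$n, c(1L, 1L))

  dup <- make_visits(list(c("I10", "I10")), date = "2019-05-01")
  fm_dup <- build_matrix(dup, 2, two_years)
  expect_equal(sum(fm_dup$n), 2L)
  fm_dd <- build_matrix(dup, 2, two_years, dedupe = TRUE)
  expect_equal(sum(fm_dd$n), 1L)
})

test_that("visits outside all partitions are excluded and counted", {
  v <- make_visits(list("I10", "E11"),
    date = c("2019-05-01", "2022-05-01")
  )
  fm <- build_matrix(v, 1, two_years)
  expect_equal(sum(fm$n), 1L)
  expect_equal(attr(fm, "n_remainder"), 1L)
})

test_that("empty inputs warn and return an all-zero matrix", {
  v <- make_visits(list(character(0)), date = "2019-05-01")
  expect_warning(fm <- build_matrix(v, 1, two_years), "empty")
  expect_equal(nrow(fm), 0)
  expect_equal(attr(fm, "periods"), c("Y2019", "Y2020"))
})

test_that("build_matrix equals the naive per-record recount", {
  v <- random_visits(600, seed = 21)
  for (level in 1:3) {
    fm <- suppressMessages(build_matrix(v, level, two_years))
    got <- dplyr::arrange(
      dplyr::filter(tibble::as_tibble(fm), n > 0), period, group
    )
    expect_equal(got, naive_matrix(v, level, two_years), ignore_attr = TRUE)
  }
  # and within a stratum
  sf <- stratum_filter(modality = "telemedicine", sex = "female")
  sub <- v[v$modality == "telemedicine" & v$sex == "female", ]
  fm_s <- suppressMessages(build_matrix(v, 2, two_years, stratum = sf))
  expect_equal(
    dplyr::arrange(dplyr::filter(tibble::as_tibble(fm_s), n > 0), period, group),
    naive_matrix(sub, 2, two_years),
    ignore_attr = TRUE
  )
})

test_that("summing finer levels through the hierarchy reproduces coarser matrices", {
  v <- random_visits(500, seed = 5)
  h <- icd_hierarchy()
  m3 <- suppressMessages(build_matrix(v, 3, two_years))
  m2 <- suppressMessages(build_matrix(v, 2, two_years))
  m1 <- suppressMessages(build_matrix(v, 1, two_years))
  expect_same_counts <- function(rolled, target) {
    j <- dplyr::full_join(rolled, tibble::as_tibble(target),
      by = c("period", "group"), suffix = c(".roll", "")
    )
    expect_equal(
      dplyr::coalesce(j$n.roll, 0L), dplyr::coalesce(j$n, 0L)
    )
  }
  # level-3 groups are category stems; push them up through the hierarchy
  roll <- function(m, to_level) {
    tibble::as_tibble(m) |>
      dplyr::mutate(
        group = suppressMessages(icd_assign_group(group, to_level, h))
      ) |>
      dplyr::group_by(period, group) |>
      dplyr::summarise(n = sum(n), .groups = "drop")
  }
  expect_same_counts(roll(m3, 2), m2)
  expect_same_counts(roll(m3, 1), m1)
  # block labels map to their chapter labels directly
  up21 <- tibble::as_tibble(m2) |>
    dplyr::mutate(group = dplyr::coalesce(
      h$blocks$chapter_label[match(group, h$blocks$label)], "UNMAPPED"
    )) |>
    dplyr::group_by(period, group) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  expect_same_counts(up21, m1)
  expect_equal(sum(m3$n), sum(m1$n))
})

test_that("stratum matrices add cell-wise to the unstratified matrix", {
  v <- random_visits(400, seed = 9)
  whole <- suppressMessages(build_matrix(v, 1, two_years))
  f2f <- suppressMessages(build_matrix(
    v, 1, two_years,
    stratum = stratum_filter(modality = "face_to_face")
  ))
  tm <- suppressMessages(build_matrix(
    v, 1, two_years,
    stratum = stratum_filter(modality = "telemedicine")
  ))
  merged <- dplyr::full_join(
    tibble::as_tibble(f2f), tibble::as_tibble(tm),
    by = c("period", "group")
  ) |>
    dplyr::mutate(n = dplyr::coalesce(n.x, 0L) + dplyr::coalesce(n.y, 0L))
  joined <- dplyr::left_join(
    tibble::as_tibble(whole), merged[c("period", "group", "n")],
    by = c("period", "group"), suffix = c("", ".sum")
  )
  expect_equal(joined$n, joined$n.sum)
})

test_that("marginal totals reproduce the published grand totals and shares", {
  fm <- ref_matrix()
  mt <- marginal_totals(fm)
  expect_equal(sum(mt$total), 3921974)
  expect_equal(partition_totals(fm)$total, c(2059441, 1862533))
  z <- mt[grepl("Z00-Z99", mt$group, fixed = TRUE), ]
  expect_equal(z$total, 483368)
  expect_equal(round(z$share_pct, 2), 12.32)

  single <- as_freq_matrix(
    tibble::tibble(label = "only", a = 3L, b = 4L),
    periods = c(P1 = "a", P2 = "b")
  )
  expect_equal(marginal_totals(single)$share_pct, 100)
})

test_that("top_k ranks by total with lexicographic ties and capped k", {
  fm <- ref_matrix()
  t5 <- top_k(fm, 5)
  expect_equal(nrow(t5), 5)
  expect_true(t5$cum_share_pct[5] > 50) # top 5 chapters exceed half of all codes
  expect_true(all(diff(t5$cum_share_pct) >= 0))
  expect_true(max(top_k(fm, 100)$cum_share_pct) <= 100 + 1e-9)
  expect_equal(nrow(top_k(fm, 100)), 21)

  tie <- as_freq_matrix(
    tibble::tibble(label = c("b group", "a group"), x = c(5L, 5L)),
    periods = c(P1 = "x")
  )
  expect_equal(top_k(tie, 2)$group, c("a group", "b group"))
  expect_error(top_k(fm, 0), "k")
})

test_that("generated level-1 shares track the configured chapter weights", {
  cfg <- synthetic_config(n_visits = c(Y2019 = 89000, Y2020 = 0))
  v <- generate_visits(cfg, seed = 101)
  fm <- build_matrix(filter_coded(v), 1, two_years)
  got <- marginal_totals(fm)
  w <- cfg$chapter_weights$Y2019
  expect_gt(sum(got$total), 90000) # ~1e5 code draws
  diff <- abs(got$share_pct / 100 - w[got$group])
  expect_true(all(diff < 0.01))
})
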