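small_config <- function(n1 = 4000, n2 = 4000, ...) {
  synthetic_config(n_visits = c(Y2019 = n1, Y2020 = n2), ...)
}

test_that("default configuration carries the published margins", {
  cfg <- synthetic_config()
  expect_equal(cfg$modality$Y2019[["face_to_face"]], 0.8530)
  expect_equal(cfg$modality$Y2020[["telemedicine"]], 0.5480)
  expect_equal(cfg$missingness[["Y2019"]], 0.1846)
  expect_equal(cfg$missingness[["Y2020"]], 0.2250)
  expect_equal(cfg$n_visits, c(Y2019 = 1421779, Y2020 = 1402406))
  for (mix in c("modality", "specialty", "sex", "age_shares")) {
    for (p in c("Y2019", "Y2020")) {
      expect_equal(sum(cfg[[mix]][[p]]), 1)
    }
  }
  expect_equal(sum(cfg$chapter_weights$Y2019), 1)
  # chapter weights are the published per-year shares
  expect_equal(
    round(100 * cfg$chapter_weights$Y2019[[
      "Factors influencing health status and contact with health services (Z00-Z99)"
    ]], 2),
    9.06
  )
})

test_that("the fitted count law hits its mean and tail targets", {
  law <- fit_code_count_law(1.38, 0.035)
  expect_equal(law$mean, 1.38)
  expect_equal(law$p_gt3, 0.035, tolerance = 1e-9)
  expect_true(law$size > 0)
  expect_error(fit_code_count_law(0.9), "exceed")
  expect_error(fit_code_count_law(1.38, 0.9), "too heavy")
})

test_that("invalid configurations are rejected before generation", {
  expect_error(
    synthetic_config(n_visits = c(Y2019 = -5, Y2020 = 10)),
    "non-negative"
  )
  expect_error(
    small_config(modality = list(
      c(face_to_face = 0.7, telemedicine = 0.2),
      c(face_to_face = 0.5, telemedicine = 0.5)
    )),
    "sums to"
  )
  expect_error(
    small_config(missingness = c(Y2019 = 1.2, Y2020 = 0.2)),
    "\\[0, 1\\]"
  )
  expect_error(
    small_config(sex = list(c(male = 1), c(male = 1))),
    "named over"
  )
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(500, 500)
  expect_identical(
    generate_visits(cfg, seed = 7), generate_visits(cfg, seed = 7)
  )
  expect_false(identical(
    generate_visits(cfg, seed = 7), generate_visits(cfg, seed = 8)
  ))
})

test_that("generated cohorts pass visit validation on round trip", {
  v <- generate_visits(small_config(300, 300), seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_visits(v, tmp)
  v2 <- read_visits(tmp)
  expect_equal(attr(v2, "n_skipped"), 0)
  expect_equal(nrow(v2), 600)
  expect_equal(
    lapply(v2$codes, unname), lapply(v$codes, unname),
    ignore_attr = TRUE
  )
})

test_that("generated structure tracks the configured rates", {
  cfg <- small_config(50000, 50000)
  v <- generate_visits(cfg, seed = 31)
  y19 <- v[format(v$date, "%Y") == "2019", ]
  # zero-code fraction within 3 binomial SE of configured missingness
  p <- cfg$missingness[["Y2019"]]
  se <- sqrt(p * (1 - p) / nrow(y19))
  expect_lt(abs(mean(lengths(y19$codes) == 0) - p), 3 * se)
  # modality mixture
  pm <- cfg$modality$Y2019[["face_to_face"]]
  se_m <- sqrt(pm * (1 - pm) / nrow(y19))
  expect_lt(abs(mean(y19$modality == "face_to_face") - pm), 3 * se_m)
  # codes-per-coded-visit law
  k <- lengths(filter_coded(y19)$codes)
  expect_lt(abs(mean(k) - 1.38), 3 * sqrt(stats::var(k) / length(k)))
  p3 <- 0.035
  expect_lt(
    abs(mean(k > 3) - p3), 3 * sqrt(p3 * (1 - p3) / length(k))
  )
  # ages stay within their bins
  expect_true(all(v$age >= 0 & v$age <= 95))
})

test_that("a 200k-code draw reproduces the configured chapter share", {
  cfg <- small_config(89000, 89000)
  v <- generate_visits(cfg, seed = 13)
  codes <- unlist(filter_coded(v)$codes)
  expect_gt(length(codes), 190000)
  y <- rep(format(v$date, "%Y"), lengths(v$codes))
  z19 <- mean(substr(codes[y == "2019"], 1, 1) == "Z")
  p <- 0.0906
  n <- sum(y == "2019")
  expect_lt(abs(z19 - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("expected counts follow the closed-form product", {
  cfg <- small_config(1000, 2000)
  em <- expected_counts(cfg, 1)
  expect_s3_class(em, "freq_matrix")
  per_period <- partition_totals(em)
  expect_equal(
    per_period$total,
    unname(cfg$n_visits * (1 - cfg$missingness) * cfg$code_law$mean),
    tolerance = 1e-9
  )
  # single-chapter config puts all mass there
  w1 <- setNames(
    c(1, rep(0, 20)), names(cfg$chapter_weights$Y2019)
  )
  cfg1 <- small_config(1000, 1000, chapter_weights = list(w1, w1))
  em1 <- expected_counts(cfg1, 1)
  expect_equal(sum(em1$n[em1$group != names(w1)[1]]), 0)
  # zero visits -> zero matrix
  cfg0 <- small_config(0, 0)
  expect_equal(sum(expected_counts(cfg0, 1)$n), 0)
  # levels conserve expected mass
  expect_equal(sum(expected_counts(cfg, 2)$n), sum(em$n), tolerance = 1e-9)
  expect_equal(sum(expected_counts(cfg, 3)$n), sum(em$n), tolerance = 1e-9)
})

test_that("the expected matrix implies the variation the configuration encodes", {
  cfg <- small_config(10000, 10000)
  evt <- variation_table(expected_counts(cfg, 1))
  # algebra on the configuration: iav from the two weights and period sizes
  tot <- cfg$n_visits * (1 - cfg$missingness) * cfg$code_law$mean
  g <- "Factors influencing health status and contact with health services (Z00-Z99)"
  manual <- 100 * (tot[["Y2020"]] * cfg$chapter_weights$Y2020[[g]] -
    tot[["Y2019"]] * cfg$chapter_weights$Y2019[[g]]) /
    (tot[["Y2019"]] * cfg$chapter_weights$Y2019[[g]])
  expect_equal(evt$iav_pct[evt$group == g], manual, tolerance = 1e-9)
  expect_equal(sum(evt$vi), 1, tolerance = 1e-12)
})

test_that("empirical variation indices recover the configured shifts", {
  cfg <- small_config(20000, 20000)
  v <- generate_visits(cfg, seed = 5)
  vt <- variation_table(build_matrix(filter_coded(v), 1, two_years))
  evt <- variation_table(expected_counts(cfg, 1))
  j <- dplyr::inner_join(
    tibble::as_tibble(vt), tibble::as_tibble(evt),
    by = "group", suffix = c("", ".exp")
  )
  expect_equal(nrow(j), 21)
  # numerator-noise bound: sd(delta) ~ sqrt(E_early + E_late)
  se_vi <- sqrt(j$n_early.exp + j$n_late.exp) / sum(abs(j$delta.exp))
  expect_true(all(abs(j$vi - j$vi.exp) < 4 * se_vi + 0.01))
})
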