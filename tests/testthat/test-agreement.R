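toy_results <- function(alg, ref) {
  alg <- as.POSIXct(alg, tz = "UTC")
  ref <- as.POSIXct(ref, tz = "UTC")
  both <- !is.na(alg) & !is.na(ref)
  d <- ifelse(both, as.integer(round(as.numeric(difftime(alg, ref, units = "mins")))),
              NA_integer_)
  tibble::tibble(patient_id = sprintf("p%02d", seq_along(alg)),
                 algorithm_time = alg, reference_time = ref,
                 diff_minutes = as.integer(d),
                 abs_diff_minutes = as.integer(abs(d)))
}

test_that("time_differences reports absolute diffs and counts exclusions", {
  res <- toy_results(c("2010-01-01 10:02", "2010-01-01 10:05", "2010-01-01 10:00"),
                     c("2010-01-01 10:02", "2010-01-01 10:03", NA))
  td <- time_differences(res)
  expect_equal(sort(td$diffs), c(0, 2))
  expect_equal(td$n_excluded, 1)
})

test_that("percent agreement reproduces the printed derivation percentages", {
  diffs <- time_differences(fixture_results("derivation"))$diffs
  expect_equal(round_half_away(percent_agreement(diffs, 0)), 87)  # 72/83
  expect_equal(round_half_away(percent_agreement(diffs, 1)), 94)  # 78/83
  expect_equal(percent_agreement(diffs, 0), 100 * 72 / 83)
  expect_equal(percent_agreement(rep(0L, 10), 0), 100)
  expect_error(percent_agreement(integer(0), 0), class = "ventzero_error")
})

test_that("agreement curve is consistent, non-decreasing, and matches validation", {
  diffs <- time_differences(fixture_results("validation"))$diffs
  curve <- agreement_curve(diffs)
  expect_true(all(diff(curve$percent) >= 0))
  at <- function(t) curve$percent_rounded[curve$tolerance_min == t]
  expect_equal(at(0), 92L)
  expect_equal(at(1), 99L)
  expect_equal(at(5), 99L)
  expect_equal(at(15), 100L)
  # single diff of 3: 0% below, 100% at or above
  c3 <- agreement_curve(3L, tolerances = c(0, 2, 3, 5))
  expect_equal(c3$percent, c(0, 0, 100, 100))
  # pointwise consistency with percent_agreement on a random multiset
  withr::with_seed(7, {
    d <- sample(0:20, 40, replace = TRUE)
    cv <- agreement_curve(d, tolerances = 0:20)
    expect_equal(cv$percent,
                 vapply(0:20, function(t) percent_agreement(d, t), numeric(1)))
  })
})

test_that("zero-chance kappa equals the observed agreement proportion", {
  diffs <- time_differences(fixture_results("derivation"))$diffs
  expect_equal(round_half_away(agreement_kappa(diffs, 0), 2), 0.87)
  expect_equal(agreement_kappa(rep(0L, 5), 0), 1)
  withr::with_seed(13, {
    for (i in seq_len(1000)) {
      d <- sample(0:30, sample(1:50, 1), replace = TRUE)
      t <- sample(0:10, 1)
      expect_identical(agreement_kappa(d, t), mean(d <= t))
    }
  })
})

test_that("minute-category kappa matches a hand-computed Cohen table", {
  # two raters, four patients; categories 10:00 (A:.5/R:.25),
  # 10:05 (.25/.5), 10:07 (.25/.25); p_o = 3/4, p_e = 0.3125
  res <- toy_results(
    c("2010-01-01 10:00", "2010-01-01 10:00", "2010-01-01 10:05", "2010-01-01 10:07"),
    c("2010-01-01 10:00", "2010-01-01 10:05", "2010-01-01 10:05", "2010-01-01 10:07"))
  expect_equal(agreement_kappa(res, 0, "minute_category"),
               (0.75 - 0.3125) / (1 - 0.3125))
  # all-perfect agreement gives 1 under both conventions
  perfect <- toy_results(rep("2010-01-01 10:00", 3), rep("2010-01-01 10:00", 3))
  expect_equal(agreement_kappa(perfect, 0, "zero_chance"), 1)
  expect_equal(agreement_kappa(perfect, 0, "minute_category"), 1)
  # chance correction can only lower kappa relative to the zero-chance form
  withr::with_seed(19, {
    for (i in seq_len(20)) {
      base <- as.POSIXct("2010-01-01 10:00", tz = "UTC")
      a <- base + sample(0:10, 12, replace = TRUE) * 60
      r <- base + sample(0:10, 12, replace = TRUE) * 60
      res <- toy_results(format(a, "%Y-%m-%d %H:%M"), format(r, "%Y-%m-%d %H:%M"))
      expect_lte(agreement_kappa(res, 2, "minute_category") + 1e-12,
                 agreement_kappa(res, 2, "zero_chance"))
    }
  })
  expect_error(agreement_kappa(c(0L, 1L), 0, "minute_category"), "paired times")
})

test_that("summarize_agreement aggregates every field and balances counts", {
  res <- fixture_results("derivation")
  s <- summarize_agreement(res)
  expect_s3_class(s, "agreement_summary")
  expect_equal(s$pct_exact, 87L)
  expect_equal(s$pct_within_1min, 94L)
  expect_equal(s$pct_within_5min, 100L)
  expect_equal(s$max_abs_diff, 5)
  expect_equal(s$kappa, 0.87)
  expect_equal(s$n_evaluable + s$n_excluded_missing, nrow(res))
  expect_true(all(diff(s$curve$percent) >= 0))

  v <- summarize_agreement(fixture_results("validation"))
  expect_equal(v$pct_exact, 92L)
  expect_equal(v$pct_within_1min, 99L)
  expect_equal(v$max_abs_diff, 15)
  expect_equal(v$kappa, 0.92)

  # a missing reference is counted, not dropped
  res2 <- res
  res2$reference_time[1] <- NA
  res2$diff_minutes[1] <- NA_integer_
  res2$abs_diff_minutes[1] <- NA_integer_
  s2 <- summarize_agreement(res2)
  expect_equal(s2$n_evaluable, 82)
  expect_equal(s2$n_excluded_missing, 1)
  expect_error(summarize_agreement(res[0, ]), class = "ventzero_error")

  out <- withr::local_tempfile(fileext = ".json")
  crv <- withr::local_tempfile(fileext = ".csv")
  write_agreement_summary(s, out, crv)
  j <- jsonlite::read_json(out)
  expect_equal(j$pct_exact, 87L)
  expect_equal(j$kappa, 0.87)
  expect_equal(nrow(readr::read_csv(crv, show_col_types = FALSE)), 10)
})

test_that("half-away-from-zero rounding reproduces all printed percentages", {
  expect_equal(round_half_away(100 * 72 / 83), 87)
  expect_equal(round_half_away(100 * 78 / 83), 94)
  expect_equal(round_half_away(100 * 65 / 71), 92)
  expect_equal(round_half_away(100 * 70 / 71), 99)
  expect_equal(round_half_away(c(0.5, 1.5, -0.5)), c(1, 2, -1))
  expect_equal(round_half_away(0.865, 2), 0.87)
})
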