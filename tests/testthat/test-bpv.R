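test_that("day and night means use the [06:00, 22:00) clock windows", {
  s <- constant_bp_series()
  m <- day_night_means(s)
  expect_equal(m$day_mean_sbp, 130)
  expect_equal(m$day_mean_dbp, 80)
  expect_equal(m$night_mean_sbp, 110)
  expect_equal(m$night_mean_dbp, 70)
  expect_identical(m$n_day + m$n_night, 48L)

  ## a reading stamped exactly 22:00 is nighttime
  one <- tibble::tibble(
    time = as.POSIXct(c("2026-01-05 12:00:00", "2026-01-05 22:00:00"),
                      tz = "UTC"),
    sbp = c(130, 999), dbp = c(80, 60))
  m2 <- day_night_means(one)
  expect_equal(m2$night_mean_sbp, 999)
  expect_equal(m2$day_mean_sbp, 130)

  ## single reading per window
  expect_equal(m2$n_day, 1L)

  hr <- as.integer(format(s$time, "%H"))
  day_only <- s[hr >= 6 & hr < 22, ]
  expect_error(day_night_means(day_only), class = "ppgbp_error_coverage")
  err <- tryCatch(day_night_means(day_only), error = identity)
  expect_match(conditionMessage(err), "night")
})

test_that("dipping classification partitions the decline axis", {
  expect_equal(as.character(classify_dipping(120, 105)$pattern), "dipper")
  expect_equal(classify_dipping(120, 105)$decline_pct, 12.5)
  expect_equal(as.character(classify_dipping(120, 114)$pattern), "nondipper")
  expect_equal(as.character(classify_dipping(120, 90)$pattern),
               "extreme-dipper")
  expect_equal(as.character(classify_dipping(120, 126)$pattern), "riser")
  ## boundary conventions: 10% -> dipper, 20% -> extreme-dipper, 0% -> nondipper
  expect_equal(as.character(classify_dipping(100, 90)$pattern), "dipper")
  expect_equal(as.character(classify_dipping(100, 80)$pattern),
               "extreme-dipper")
  expect_equal(as.character(classify_dipping(100, 100)$pattern), "nondipper")
  expect_error(classify_dipping(0, 90), class = "ppgbp_error_input")
  ## exactly one label for any decline
  decl <- seq(-30, 40, by = 0.5)
  lab <- classify_dipping(rep(100, length(decl)), 100 - decl)$pattern
  expect_false(anyNA(lab))
})

test_that("generated series classify back to the requested pattern", {
  for (pat in c("dipper", "nondipper", "extreme-dipper", "riser")) {
    for (seed in c(1, 7, 23)) {
      s <- synthesize_bp_series(pat, day_mean = 125, seed = seed)
      expect_equal(as.character(dipping_pattern(s)$pattern), pat)
    }
  }
})

test_that("daily statistics return the four Table-style summaries", {
  times <- as.POSIXct("2026-01-05 08:00:00", tz = "UTC") + (0:2) * 3600
  s <- tibble::tibble(time = times, sbp = c(118, 130, 142),
                      dbp = c(70, 82, 76))
  d <- daily_stats(s, "2026-01-05")
  expect_equal(d$mean_sbp, 130)
  expect_equal(d$max_sbp, 142)
  expect_equal(d$mean_dbp, 76)
  expect_equal(d$min_dbp, 70)
  one <- daily_stats(s[2, ], "2026-01-05")
  expect_equal(unlist(one[c("mean_sbp", "max_sbp")]), c(130, 130),
               ignore_attr = TRUE)
  expect_error(daily_stats(s, "2026-01-06"), class = "ppgbp_error_coverage")
})

test_that("histogram counts conserve readings and use half-open bins", {
  withr::with_seed(9, {
    s <- tibble::tibble(
      time = as.POSIXct("2026-01-05", tz = "UTC") + seq_len(10) * 600,
      sbp = runif(10, 95, 165), dbp = runif(10, 60, 90))
  })
  h <- bp_histogram(s, bin_width = 10)
  expect_equal(sum(h$count), 10)
  ## edge reading falls in the bin whose lower edge it matches
  s2 <- s
  s2$sbp <- c(rep(100, 5), rep(110, 5))
  h2 <- bp_histogram(s2, bin_width = 10, range = c(90, 120))
  expect_equal(h2$count[h2$bin_lo == 100], 5)
  expect_equal(h2$count[h2$bin_lo == 110], 5)
  expect_equal(h2$count[h2$bin_lo == 90], 0)
  empty <- s[0, ]
  he <- bp_histogram(empty, bin_width = 10, range = c(90, 120))
  expect_true(all(he$count == 0))
  expect_error(bp_histogram(s, bin_width = 0), class = "ppgbp_error_input")
})

test_that("weekly extremes match a brute-force per-day scan", {
  withr::with_seed(10, {
    times <- as.POSIXct("2026-01-05 00:00:00", tz = "UTC") +
      seq(0, by = 3600, length.out = 7 * 24)
    s <- tibble::tibble(time = times,
                        sbp = round(runif(length(times), 100, 170)),
                        dbp = round(runif(length(times), 55, 95)))
  })
  w <- weekly_stats(s)
  expect_identical(as.character(w$weekday[1]), "Monday")  # series starts Monday
  for (i in seq_len(nrow(w))) {
    sel <- weekdays(as.Date(s$time)) == as.character(w$weekday[i])
    expect_equal(w$max_sbp[i], max(s$sbp[sel]))
    expect_equal(w$min_dbp[i], min(s$dbp[sel]))
  }
  ## a single-day series yields a single weekday key
  tue <- dplyr::filter(s, as.Date(time) == as.Date("2026-01-06"))
  expect_identical(nrow(weekly_stats(tue)), 1L)
  ## two Mondays pool their readings
  s14 <- dplyr::bind_rows(s, dplyr::mutate(s, time = time + 7 * 86400,
                                           sbp = sbp + 5))
  w14 <- weekly_stats(s14)
  mon <- weekdays(as.Date(s14$time)) == "Monday"
  expect_equal(w14$max_sbp[w14$weekday == "Monday"], max(s14$sbp[mon]))
})

test_that("helper formulas: BMI and calories", {
  expect_equal(bmi(72, 1.8), 72 / 1.8^2)
  expect_equal(calories_from_steps(10000), 400)
  expect_equal(calories_from_steps(10000, kcal_per_step = 0.05), 500)
})
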