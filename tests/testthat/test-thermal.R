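test_that("series construction validates the hourly grid", {
  expect_error(hourly_temps(character(0), numeric(0)), "empty")
  ts <- seq(as.POSIXct("2017-11-01", tz = "UTC"), by = 3600, length.out = 5)
  expect_error(hourly_temps(ts[c(1, 2, 4, 5)], rep(5, 4)), "1-hour step")
  expect_error(hourly_temps(ts, c(5, 5, NA, 5, 5)), "non-finite")
  s <- hourly_temps(ts, 1:5)
  expect_s3_class(s, "hourly_temps")
  expect_equal(nrow(s), 5)
})

test_that("gap filling interpolates short gaps and refuses long ones", {
  ts <- seq(as.POSIXct("2017-11-01", tz = "UTC"), by = 3600, length.out = 10)
  df <- data.frame(timestamp = ts[-c(4, 5)], temp_c = c(1, 2, 3, 6, 7, 8, 9, 10))
  filled <- fill_temperature_gaps(df)
  expect_equal(nrow(filled), 10)
  expect_equal(filled$temp_c, 1:10)   # linear gap closes exactly
  long <- data.frame(timestamp = ts[c(1, 10)], temp_c = c(0, 9))
  expect_error(fill_temperature_gaps(long), "gap")
  expect_warning(fill_temperature_gaps(long, allow_long_gaps = TRUE),
                 "interpolated")
})

test_that("chilling hours credit the open-closed 0-7.2 band", {
  expect_equal(chilling_hours(make_series(5))$incremental, 1)
  expect_equal(chilling_hours(make_series(10))$incremental, 0)
  expect_equal(tail(chilling_hours(make_series(rep(5, 24)))$cumulative, 1), 24)
  # boundary convention: open at low, closed at high
  expect_equal(chilling_hours(make_series(c(0, 7.2, 7.3)))$incremental,
               c(0, 1, 0))
  expect_error(chilling_hours(make_series(5), low = 8, high = 2), "low < high")
})

test_that("chill portions match the hour-by-hour oracle transcription", {
  # warm hours never complete the intermediate
  expect_equal(tail(chill_portions(make_series(rep(30, 240)))$cumulative, 1), 0)
  # frozen oracle value for ten days at constant 6 degC
  v <- tail(chill_portions(make_series(rep(6, 240)))$cumulative, 1)
  expect_equal(v, 7.820745749815, tolerance = 1e-9)
  expect_equal(v, tail(oracle_chill_portions(rep(6, 240)), 1),
               tolerance = 1e-12)
  # random series equivalence
  set.seed(7)
  temps <- runif(1000, -15, 30)
  expect_lt(max(abs(chill_portions(make_series(temps))$cumulative -
                      oracle_chill_portions(temps))), 1e-9)
})

test_that("GDH response is zero outside cardinal temperatures and peaks at the optimum", {
  p <- gdh_params(4, 25, 36, 1)
  inc <- growing_degree_hours(make_series(c(4, 25, 36, 40, -3)), p)$incremental
  expect_equal(inc, c(0, 21, 0, 0, 0), tolerance = 1e-9)
  # continuity at the optimum: both branches evaluate to (t_opt - t_base)
  eps <- 1e-9
  lo <- buddorm:::gdh_hourly(25 - eps, p)
  hi <- buddorm:::gdh_hourly(25 + eps, p)
  expect_equal(lo, 21, tolerance = 1e-6)
  expect_equal(hi, 21, tolerance = 1e-6)
  expect_equal(buddorm:::gdh_hourly(36 - 1e-10, p), 0, tolerance = 1e-6)
  expect_error(gdh_params(25, 4, 36), "t_base < t_optimal")
  expect_error(gdh_params(4, 25, 36, stress_factor = 0), "stress_factor")
})

test_that("accumulations are non-decreasing, reproducible and shift-invariant", {
  set.seed(11)
  temps <- runif(500, -10, 25)
  s1 <- make_series(temps)
  s2 <- hourly_temps(s1$timestamp + 86400 * 30, temps)
  for (fn in list(chilling_hours, chill_portions, growing_degree_hours)) {
    a1 <- fn(s1); a2 <- fn(s2)
    expect_true(all(diff(a1$cumulative) >= 0))
    expect_true(all(a1$incremental >= 0))
    expect_equal(a1$cumulative, cumsum(a1$incremental), tolerance = 1e-9)
    expect_identical(a1$incremental, fn(s1)$incremental)  # bitwise repeat
    expect_identical(a1$incremental, a2$incremental)      # time-shift
  }
  ch <- chilling_hours(s1)
  expect_true(all(ch$cumulative == round(ch$cumulative)))
})

test_that("interval accumulation is additive and conserves the total", {
  set.seed(3)
  s <- make_series(runif(400, -5, 15))
  acc <- chilling_hours(s)
  t0 <- s$timestamp[1] - 3600
  tn <- s$timestamp[400]
  expect_equal(accumulate_between(acc, t0, t0), 0)
  expect_equal(accumulate_between(acc, t0, tn), tail(acc$cumulative, 1))
  for (cut in sample(2:399, 20)) {
    tm <- s$timestamp[cut]
    expect_equal(accumulate_between(acc, t0, tm) +
                   accumulate_between(acc, tm, tn),
                 accumulate_between(acc, t0, tn))
  }
  expect_error(accumulate_between(acc, t0 - 86400, tn), "outside")
  expect_error(accumulate_between(acc, tn, t0), "start")
})

test_that("windowed chill sums cover whole calendar-day windows", {
  s <- make_series(rep(5, 24 * 30), start = "2017-11-01 00:00:00")
  acc <- chilling_hours(s)
  expect_equal(as.numeric(windowed_chill_sum(acc, "2017-11-20", 14)), 336)
  # two consecutive 7-day windows sum to the 14-day window
  w7a <- windowed_chill_sum(acc, "2017-11-13", 7)
  w7b <- windowed_chill_sum(acc, "2017-11-20", 7)
  expect_equal(as.numeric(w7a) + as.numeric(w7b), 336)
  warm <- chilling_hours(make_series(rep(20, 24 * 20)))
  expect_equal(as.numeric(windowed_chill_sum(warm, "2017-11-16", 14)), 0)
  # truncation policy
  expect_error(windowed_chill_sum(acc, "2017-11-05", 14), "truncate")
  tr <- windowed_chill_sum(acc, "2017-11-05", 14, partial = "truncate")
  expect_true(attr(tr, "truncated"))
  expect_equal(as.numeric(tr), 5 * 24)
  expect_error(windowed_chill_sum(acc, "2016-01-01", 14), "outside")
})

test_that("mean daily temperature averages full days only", {
  s <- make_series(rep(3, 48))
  expect_equal(mean_daily_temperature(s, "2017-11-01"), 3)
  s2 <- make_series(rep(c(0, 10), each = 12))
  expect_equal(mean_daily_temperature(s2, "2017-11-01"), 5)
  # sinusoidal day integrates back to its mean parameter
  h <- 0:23
  s3 <- make_series(7 + 4 * cos(2 * pi * (h - 14) / 24))
  expect_equal(mean_daily_temperature(s3, "2017-11-01"), 7, tolerance = 1e-9)
  expect_error(mean_daily_temperature(s, "2018-01-01"), "absent")
  partial <- make_series(rep(5, 10))
  expect_error(mean_daily_temperature(partial, "2017-11-01"), "minimum")
})
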