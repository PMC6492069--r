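test_that("feature naming is stable: 13 basic + 117 extended = 130", {
  fn <- feature_names()
  expect_length(fn, 130)
  expect_length(unique(fn), 130)
  expect_identical(fn[1], "steps_during_bedtime")
  expect_true(all(c("HR_CR_acrophase_12d_gradient", "sleep_length_3d_mean",
                    "resting_heart_rate_6d_stdev") %in% fn))
})

make_manual_bundle <- function(steps = NULL, light = NULL, sleep = NULL,
                               hr = NULL, dates = as.Date("2015-06-10")) {
  site <- test_site()
  empty_ts <- function(col) {
    dt <- data.table(timestamp = as.POSIXct(character(), tz = "UTC"),
                     v = numeric())
    setnames(dt, "v", col)
  }
  new_bundle("X",
             hr %||% empty_ts("bpm"), steps %||% empty_ts("steps"),
             light %||% empty_ts("lux"),
             sleep %||% data.table(date = as.Date(character()),
                                   onset = as.POSIXct(character(), tz = "UTC"),
                                   offset = as.POSIXct(character(), tz = "UTC"),
                                   efficiency = numeric()),
             data.table(date = dates, score = 0L),
             data.table(patient_id = character(), start = as.Date(character()),
                        end = as.Date(character()), type = character()),
             site)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("steps inside the daytime window sum; an event-free bedtime is 0", {
  site <- test_site()
  d <- as.Date("2015-06-10")
  dw <- daytime_window(d, site)
  # 100 steps/min over the full daytime window only
  n_min <- floor(as.numeric(dw$end - dw$start, units = "mins"))
  ts <- dw$start + (seq_len(n_min) - 1) * 60
  b <- make_manual_bundle(steps = data.table(timestamp = ts,
                                             steps = rep(100L, n_min)))
  bf <- daily_basic_features(b, dates = d)
  expect_equal(bf$steps_during_daytime, 100 * n_min)
  # tracker was worn that day, so the empty bedtime slot counts 0, not NA
  expect_equal(bf$steps_during_bedtime, 0)
})

test_that("light averages within its window; an empty slot is missing", {
  site <- test_site()
  d <- as.Date("2015-06-10")
  bw <- bedtime_window(d - 1, site) # night ending at sunrise(d)
  ts <- seq(bw$start, bw$end - 1, by = "30 min")
  b <- make_manual_bundle(light = data.table(timestamp = ts,
                                             lux = rep(50, length(ts))))
  bf <- daily_basic_features(b, dates = d)
  expect_equal(bf$light_exposure_during_bedtime, 50)
  expect_true(is.na(bf$light_exposure_during_daytime))
})

test_that("sleep timing deviation is circular", {
  site <- test_site()
  dates <- as.Date("2015-06-01") + 0:7
  midn <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  mk_sleep <- function(onsets) {
    data.table(date = dates,
               onset = midn - 86400 + onsets * 3600,
               offset = midn + 7.5 * 3600, efficiency = 90)
  }
  # constant 23:00 schedule: deviation 0 on day 8
  s <- mk_sleep(rep(23, 8))
  expect_equal(sleep_timing_dev(s, dates[8], "onset", site), 0)
  # preceding week at 23:00, today 01:00 (clock 25h): 2 h, not 22 h
  s2 <- mk_sleep(c(rep(23, 7), 25))
  expect_equal(sleep_timing_dev(s2, dates[8], "onset", site), 2)
  # fewer than 3 history records: missing
  s3 <- mk_sleep(rep(23, 8))[c(1, 8)]
  expect_true(is.na(sleep_timing_dev(s3, dates[8], "onset", site)))
})

test_that("random schedules match a trigonometric-embedding oracle", {
  site <- test_site()
  set.seed(55)
  dates <- as.Date("2015-06-01") + 0:7
  midn <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  for (rep_i in 1:5) {
    onsets <- runif(8, 21, 27) # spans midnight
    s <- data.table(date = dates, onset = midn - 86400 + onsets * 3600,
                    offset = midn + 7.5 * 3600, efficiency = 90)
    got <- sleep_timing_dev(s, dates[8], "onset", site)
    # oracle: embed clock times on the unit circle
    a <- (onsets %% 24) * 2 * pi / 24
    mu <- atan2(mean(sin(a[1:7])), mean(cos(a[1:7])))
    dlt <- abs(atan2(sin(a[8] - mu), cos(a[8] - mu))) * 24 / (2 * pi)
    expect_equal(got, dlt, tolerance = 1e-9)
  }
})

test_that("windowed statistics follow the stated arithmetic", {
  co <- noiseless_cohort()
  basic <- daily_basic_features(co$bundles[[1]])
  # overwrite one series with a known ramp to pin the window arithmetic
  basic[, steps_during_daytime := seq_len(.N) * 2] # 2, 4, 6, ...
  ext <- extend_features(basic)
  r <- ext[3] # days 1..3 hold 2, 4, 6
  expect_equal(r$steps_during_daytime_3d_mean, 4)
  expect_equal(r$steps_during_daytime_3d_stdev, 2)
  expect_equal(r$steps_during_daytime_3d_gradient, 2)
  # constant series: stdev and gradient vanish, mean is the constant
  basic2 <- copy(basic)[, sleep_efficiency := 92]
  ext2 <- extend_features(basic2)
  expect_true(all(ext2$sleep_efficiency_6d_stdev[-(1:5)] == 0))
  expect_true(all(ext2$sleep_efficiency_6d_gradient[-(1:5)] == 0))
  expect_true(all(ext2$sleep_efficiency_6d_mean[-(1:5)] == 92))
  # any missing constituent day poisons the window statistic
  basic3 <- copy(basic)
  basic3[5, sleep_length := NA]
  ext3 <- extend_features(basic3)
  expect_true(all(is.na(ext3$sleep_length_3d_mean[5:7])))
  expect_false(is.na(ext3$sleep_length_3d_mean[8]))
})

test_that("every complete row carries exactly 130 feature values", {
  fm <- build_feature_matrix(small_cohort()$bundles)
  expect_true(all(feature_names() %in% names(fm)))
  vals <- fm[complete == TRUE, .SD, .SDcols = feature_names()]
  expect_equal(ncol(vals), 130)
  expect_false(anyNA(vals))
})

test_that("acrophase window statistics respect the 24-h circle", {
  co <- noiseless_cohort()
  basic <- daily_basic_features(co$bundles[[1]])
  # phases hugging midnight: 23.9, 0.1, 23.9, ... must not look like 12 +/- jumps
  basic[, HR_CR_acrophase := rep(c(23.9, 0.1), length.out = .N)]
  ext <- extend_features(basic)
  ok <- !is.na(ext$HR_CR_acrophase_3d_stdev)
  expect_true(all(ext$HR_CR_acrophase_3d_stdev[ok] < 0.5))
  m <- ext$HR_CR_acrophase_3d_mean[!is.na(ext$HR_CR_acrophase_3d_mean)]
  expect_true(all(m >= 0 & m < 24))
  expect_true(all(pmin(m, 24 - m) < 0.5)) # near midnight, not near noon
})

test_that("no feature for day d reads data after the end of day d", {
  co <- small_cohort()
  b <- co$bundles[[1]]
  fm_full <- build_feature_matrix(b)
  cut <- as.Date("2015-04-05") # mid-cohort
  site <- b$site
  end_of_day <- as.POSIXct(paste(cut + 1, "00:00:00"), tz = "UTC")
  trunc <- new_bundle(b$patient_id,
                      b$hr[timestamp < end_of_day],
                      b$steps[timestamp < end_of_day],
                      b$light[timestamp < end_of_day],
                      b$sleep[date <= cut], b$mood[date <= cut],
                      b$episodes, site)
  fm_trunc <- build_feature_matrix(trunc)
  a <- fm_full[date <= cut, .SD, .SDcols = feature_names()]
  b2 <- fm_trunc[date <= cut, .SD, .SDcols = feature_names()]
  expect_equal(as.data.frame(b2), as.data.frame(a))
})
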