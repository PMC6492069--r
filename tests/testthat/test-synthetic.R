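test_that("invalid configurations are refused", {
  bad <- default_transition(); bad[1, 1] <- 0.5 # row no longer sums to 1
  expect_error(sim_config(transition = bad), "transition matrix")
  expect_error(sim_config(coupling = -1), "coupling")
  expect_error(sim_config(hr_amplitude = -2), "hr_amplitude")
  expect_error(sim_config(missing_rates = c(sleep = 1.2)), "missing_rates")
  expect_warning(simulate_cohort(sim_config(n_patients = 1, n_days = 5, seed = 1)),
                 "n_days < 13")
})

test_that("identical (config, seed) reproduces the cohort exactly", {
  cfg <- sim_config(n_patients = 2, n_days = 15, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  for (p in seq_along(a$bundles)) {
    for (s in c("hr", "steps", "light", "sleep", "mood", "episodes")) {
      expect_identical(a$bundles[[p]][[s]], b$bundles[[p]][[s]])
    }
  }
  # and a different seed differs
  c <- simulate_cohort(sim_config(n_patients = 2, n_days = 15, seed = 100))
  expect_false(identical(a$bundles[[1]]$hr$bpm, c$bundles[[1]]$hr$bpm))
})

test_that("noiseless uncoupled world reproduces the configured rhythm", {
  co <- noiseless_cohort()
  tr <- co$truth
  expect_true(all(tr$true_mesor == 70))
  expect_true(all(tr$true_amplitude == 10))
  expect_true(all(tr$true_acrophase == 15))
  fm <- build_feature_matrix(co$bundles)
  expect_equal(fm$HR_CR_mesor, rep(70, nrow(fm)), tolerance = 1e-6)
  expect_equal(fm$HR_CR_amplitude, rep(10, nrow(fm)), tolerance = 1e-6)
  expect_equal(fm$HR_CR_acrophase, rep(15, nrow(fm)), tolerance = 1e-6)
  expect_equal(fm$HR_CR_rsquared, rep(1, nrow(fm)), tolerance = 1e-6)
})

test_that("instability is higher inside episodes and mood follows polarity", {
  co <- cached("occupancy_cohort",
               simulate_cohort(sim_config(n_patients = 3, n_days = 2000,
                                          hr_noise_sd = 0, seed = 17)))
  tr <- co$truth
  expect_gt(mean(tr$instability[tr$episode_state != "NE"]),
            mean(tr$instability[tr$episode_state == "NE"]))
  moods <- rbindlist(lapply(co$bundles, function(b)
    cbind(patient_id = b$patient_id, b$mood)))
  j <- moods[tr, on = c("patient_id", "date")]
  expect_lt(mean(j$score[j$episode_state == "DE"]), 0)
  expect_gt(mean(j$score[j$episode_state %in% c("ME", "HME")]), 0)
})

test_that("episode occupancy matches the stationary distribution", {
  co <- cached("occupancy_cohort",
               simulate_cohort(sim_config(n_patients = 3, n_days = 2000,
                                          hr_noise_sd = 0, seed = 17)))
  tm <- default_transition()
  ev <- eigen(t(tm))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  occ <- prop.table(table(factor(co$truth$episode_state,
                                 levels = colnames(tm))))
  # episodes last ~a month, so 6000 patient-days ~ 100 independent sojourns
  expect_true(all(abs(as.numeric(occ) - stat) < 0.08))
})

test_that("missingness injection is day-granular and seed-stable", {
  co <- simulate_cohort(sim_config(n_patients = 1, n_days = 30,
                                   hr_noise_sd = 0, seed = 5))
  b <- co$bundles[[1]]
  # identity at rate 0
  b0 <- inject_missingness(b, c(sleep = 0, hr = 0), seed = 1)
  expect_identical(b0$sleep, b$sleep)
  expect_identical(b0$hr, b$hr)
  # rate validation
  expect_error(inject_missingness(b, c(sleep = 2), seed = 1), "\\[0,1\\]")
  expect_error(inject_missingness(b, c(gps = 0.5), seed = 1), "unknown stream")
  # full removal of a stream
  b1 <- inject_missingness(b, c(sleep = 1), seed = 1)
  expect_equal(nrow(b1$sleep), 0)
  # day-granular: every surviving day keeps its full 1440-minute grid
  b2 <- inject_missingness(b, c(hr = 0.3), seed = 7)
  site <- b$site
  per_day <- table(format(b2$hr$timestamp, "%Y-%m-%d", tz = "UTC"))
  expect_true(all(per_day == 1440))
  expect_identical(inject_missingness(b, c(hr = 0.3), seed = 7)$hr, b2$hr)
})

test_that("complete-row count under sleep missingness matches a per-day scan", {
  cfg <- sim_config(n_patients = 1, n_days = 100, seed = 31,
                    missing_rates = c(sleep = 0.2))
  co <- simulate_cohort(cfg)
  b <- co$bundles[[1]]
  fm <- build_feature_matrix(b)

  # oracle: enumerate days, independently of the feature pipeline
  all_dates <- seq(cfg$start_date, cfg$start_date + cfg$n_days - 1L, by = "day")
  has_sleep <- all_dates %in% as.Date(b$sleep$date)
  basic_ok <- vapply(seq_along(all_dates), function(i) {
    d <- all_dates[i]
    hist <- sum(as.Date(b$sleep$date) >= d - 7 & as.Date(b$sleep$date) <= d - 1)
    has_sleep[i] && hist >= 3
  }, logical(1))
  # a row is complete iff the trailing 12 days (incl. d) are all basic-complete
  row_ok <- vapply(seq_along(all_dates), function(i) {
    if (i < 12) return(FALSE) # 12-day window needs 11 predecessors
    all(basic_ok[(i - 11):i])
  }, logical(1))

  expect_identical(fm$complete, row_ok)
  expect_equal(sum(fm$complete), sum(row_ok))
})

test_that("total sleep removal leaves zero complete feature rows", {
  co <- simulate_cohort(sim_config(n_patients = 1, n_days = 20, seed = 13,
                                   missing_rates = c(sleep = 1)))
  fm <- build_feature_matrix(co$bundles)
  expect_equal(sum(fm$complete), 0)
})
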