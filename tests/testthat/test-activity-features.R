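test_that("study-day assignment follows the night-attribution convention", {
  cal <- default_cal
  at <- function(day, hms) as.POSIXct(cal$induction_date, tz = "UTC") +
    day * 86400 + hms[1] * 3600 + hms[2] * 60
  # 23:00 on day 3's date -> night of day 3
  r <- assign_study_day(at(3, c(23, 0)), cal)
  expect_equal(r$study_day, 3L); expect_true(r$dark)
  # 02:00 on day 4's date -> still the night that began on day 3
  r <- assign_study_day(at(4, c(2, 0)), cal)
  expect_equal(r$study_day, 3L); expect_true(r$dark)
  # noon on day 3's date -> day 3, light cycle
  r <- assign_study_day(at(3, c(12, 0)), cal)
  expect_equal(r$study_day, 3L); expect_false(r$dark)
  # boundary instants: lights_off starts the night, lights_on ends it
  expect_true(assign_study_day(at(3, c(18, 0)), cal)$dark)
  expect_false(assign_study_day(at(3, c(6, 0)), cal)$dark)
  expect_error(assign_study_day(at(-5, c(23, 0)), cal),
               class = "daindex_domain_error")
})

test_that("daily salient feature matches brute-force oracles for every method", {
  # constant night: every method returns the constant
  tr <- constant_night_trace("a", 3, 20)
  for (m in c("q99", "max", "mean")) {
    f <- daily_salient_feature(tr, 3, method = m)
    expect_equal(f$value, 20)
    expect_equal(f$coverage, 1)
  }
  # enumerated per-minute speeds 1..720
  tr2 <- make_night_trace("a", list(`5` = 1:720))
  expect_equal(daily_salient_feature(tr2, 5, method = "max")$value, 720)
  # nearest-rank oracle: sort and index
  oracle_q99 <- sort(1:720)[ceiling(0.99 * 720)]
  expect_equal(daily_salient_feature(tr2, 5, method = "q99")$value, oracle_q99)
  expect_equal(oracle_q99, 713)
  expect_error(daily_salient_feature(tr2, 5, method = "median"),
               class = "daindex_config_error")
})

test_that("q99 and max agree with sort-based oracles on random short vectors", {
  withr::with_seed(42, {
    for (i in 1:50) {
      n <- sample(1:100, 1)
      x <- round(runif(n, 0, 50), 3)
      expect_equal(nearest_rank_quantile(x, 0.99), sort(x)[ceiling(0.99 * n)])
      expect_equal(nearest_rank_quantile(x, 1), max(x))
    }
  })
})

test_that("low-coverage nights are reported missing and never contribute downstream", {
  ts <- night_timestamps(2)[1:72]  # 10% of the night present
  tr <- tibble::tibble(animal_id = "a", timestamp = ts, speed_mm_s = 25)
  f <- daily_salient_feature(tr, 2)
  expect_equal(f$coverage, 0.1)
  expect_true(is.na(f$value))

  # such a night is excluded from the baseline mean
  full <- dplyr::bind_rows(tr, constant_night_trace("a", c(-2, -1, 1, 3), 22))
  full <- full[order(full$timestamp), ]
  feats <- daily_features(full)
  base <- baseline_feature(feats)
  expect_equal(base$baseline_value, 22)
  expect_equal(base$n_days_used, 4L)
})

test_that("baseline is the window mean and always excludes induction day 0", {
  feats <- tibble::tibble(animal_id = "a",
                          study_day = c(-2, -1, 0, 1),
                          value = c(20, 22, 5, 24), coverage = 1)
  base <- baseline_feature(feats)
  expect_equal(base$baseline_value, 22)   # day 0's value 5 is ignored
  expect_equal(base$n_days_used, 3L)

  all22 <- tibble::tibble(animal_id = "a", study_day = -2:5, value = 22,
                          coverage = 1)
  expect_equal(baseline_feature(all22)$baseline_value, 22)

  short <- tibble::tibble(animal_id = "a", study_day = c(-2, -1),
                          value = 22, coverage = 1)
  expect_warning(out <- baseline_feature(short), "usable baseline days")
  expect_equal(nrow(out), 0)
})

test_that("the DAI is the clamped scaled activity deficit", {
  expect_equal(compute_dai(22, 22), 0)
  expect_equal(compute_dai(11, 22), 10)
  expect_equal(compute_dai(0.57 * 22, 22), 8.6)
  expect_equal(compute_dai(30, 22), 0)           # above baseline clamps to 0
  expect_true(is.na(compute_dai(NA_real_, 22)))  # missing propagates
  expect_error(compute_dai(10, 0), class = "daindex_domain_error")
})

test_that("DAI is non-increasing in the daily feature at fixed baseline", {
  withr::with_seed(1, {
    for (i in 1:20) {
      base <- runif(1, 10, 40)
      v <- sort(runif(50, 0, 1.5 * base))
      d <- compute_dai(v, base)
      expect_true(all(diff(d) <= 1e-12))
      expect_true(all(d >= 0))
    }
  })
})

test_that("DAI over the baseline window of a healthy animal is near zero", {
  cfg <- sim_config(seed = 9)
  study <- simulate_cohort(cfg, list(group_spec("Control", 3, induced = FALSE)))
  feats <- daily_features(study$traces)
  base <- baseline_feature(feats)
  d <- dai_series(feats, base)
  win <- d$dai[d$study_day %in% baseline_days(study_calendar())]
  cv <- cfg$baseline_dark_speed_sd / cfg$baseline_dark_speed_mean
  expect_lt(abs(mean(win, na.rm = TRUE)), 20 * cv)
  # and missing days propagate as missing DAI
  feats$value[feats$study_day == 10] <- NA
  d2 <- dai_series(feats, base)
  expect_true(all(is.na(d2$dai[d2$study_day == 10])))
})

test_that("mean night motion pools dark samples across the requested days", {
  tr <- constant_night_trace("a", -3:-1, 21.7)
  expect_equal(mean_night_motion(tr, -3:-1), 21.7)
  two <- dplyr::bind_rows(constant_night_trace("a", 1, 20),
                          constant_night_trace("a", 2, 24))
  expect_equal(mean_night_motion(two, 1:2), 22)
  expect_warning(v <- mean_night_motion(tr, 10), "no dark-cycle samples")
  expect_true(is.na(v))

  cfg <- sim_config(seed = 5)
  withr::with_seed(5, {
    st <- latent_state("c", cfg, NA, 0)
    sim <- simulate_trace(st, cfg)
  })
  pooled <- mean_night_motion(sim, 13:17)
  se <- cfg$baseline_dark_speed_sd / sqrt(5 * 720)
  expect_lt(abs(pooled - 22.0), 3 * se)
})

test_that("percent decrease reproduces the reported activity declines", {
  expect_equal(percent_decrease(21.7, 18.6), 14)
  expect_equal(percent_decrease(22.3, 22.3), 0)
  expect_equal(percent_decrease(22.3, 12.4), 44)
  expect_error(percent_decrease(0, 5), class = "daindex_domain_error")
})
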