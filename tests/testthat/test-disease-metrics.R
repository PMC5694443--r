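test_that("onset is the earliest day sustained above threshold", {
  expect_equal(detect_onset(10:14, c(1, 2, 6, 7, 8), 5), 12L)
  # a one-day excursion on day 11 is a blip, not onset
  expect_equal(detect_onset(10:14, c(1, 6, 2, 6, 7), 5), 13L)
  expect_true(is.na(detect_onset(10:14, c(1, 2, 3, 4, 5), 5)))
  # exceedance only on the final observed day still counts
  expect_equal(detect_onset(10:14, c(1, 1, 1, 1, 9), 5), 14L)
  expect_error(detect_onset(integer(0), numeric(0), 5),
               class = "daindex_domain_error")
})

test_that("onset detector matches the exhaustive oracle on 1000 random series", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      n <- sample(3:18, 1)
      days <- sort(sample(0:17, n))
      values <- round(runif(n, 0, 10), 1)
      values[runif(n) < 0.1] <- NA
      if (all(is.na(values))) values[1] <- 1
      expect_identical(detect_onset(days, values, 5),
                       as.integer(oracle_onset(days, values, 5)))
    }
  })
})

test_that("incidence uses a strict comparison over any observed day", {
  expect_false(call_incidence(1:3, c(1, 5, 3), 5))   # equality is not above
  expect_true(call_incidence(10, 5.1, 5))
  expect_error(call_incidence(1:2, c(NA, NA), 5), class = "daindex_domain_error")
})

test_that("no control animal in a default cohort is ever called arthritic by DAI", {
  study <- simulate_cohort(sim_config(seed = 11),
                           list(group_spec("Control", 16, induced = FALSE)))
  feats <- daily_features(study$traces)
  d <- dai_series(feats, baseline_feature(feats))
  hits <- vapply(split(d, d$animal_id), function(a) {
    keep <- a$study_day >= 0
    call_incidence(a$study_day[keep], a$dai[keep], 5)
  }, logical(1))
  expect_equal(sum(hits), 0L)
})

test_that("severity is the end-of-study value, or the day-0 change for joints", {
  expect_equal(severity_at_end(13:17, c(5, 6, 8, 9, 9.7), "dai"), 9.7)
  expect_equal(severity_at_end(c(0, 10, 17), c(0.22, 0.30, 0.33), "joint"), 0.11)
  # censoring truncates to the endpoint day
  expect_equal(severity_at_end(13:17, c(5, 6, 8, 9, 9.7), "dai", censor_day = 15), 8)
  # an unobserved censor day falls back to the last prior observation
  expect_message(v <- severity_at_end(c(13, 14, 16), c(5, 6, 7), "dai",
                                      censor_day = 15),
                 "last prior observation")
  expect_equal(v, 6)
  expect_error(severity_at_end(c(1, 17), c(0.22, 0.33), "joint"),
               class = "daindex_domain_error")
})

test_that("cumulative burden equals the day-by-day oracle", {
  expect_equal(cumulative_over_threshold(1:3, c(6, 7, 4), 5), 3)
  expect_equal(cumulative_over_threshold(1:3, c(1, 2, 3), 5), 0)
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(1:18, 1)
      values <- round(runif(n, 0, 10), 2)
      thr <- runif(1, 1, 9)
      acc <- 0
      for (v in values) acc <- acc + max(0, v - thr)   # explicit accumulation
      expect_equal(cumulative_over_threshold(seq_len(n), values, thr), acc)
    }
  })
})

test_that("humane-endpoint criteria censor at the earliest firing day", {
  rec <- function(days, joint = 0.3, paw = 0, weight = 250) {
    tibble::tibble(animal_id = "a",
                   study_day = rep(days, 5),
                   metric = rep(c("joint_left_in", "joint_right_in",
                                  "paw_score_left", "paw_score_right",
                                  "body_weight_g"), each = length(days)),
                   value = c(rep_len(joint, length(days)),
                             rep_len(joint, length(days)),
                             rep_len(paw, length(days)),
                             rep_len(paw, length(days)),
                             rep_len(weight, length(days))))
  }
  # joint limit fires at >= 0.4 exactly
  r <- rec(10:17, joint = c(0.3, 0.3, 0.3, 0.3, 0.40, 0.42, 0.42, 0.42))
  expect_equal(apply_humane_endpoint(r), 14L)
  # maximal paw score for only two days does not exceed 48 h
  r <- rec(10:17, paw = c(0, 0, 0, 4, 4, 0, 0, 0))
  expect_true(is.na(apply_humane_endpoint(r)))
  # three consecutive maximal days fire on the third
  r <- rec(10:17, paw = c(0, 0, 0, 4, 4, 4, 0, 0))
  expect_equal(apply_humane_endpoint(r), 15L)
  # >20% weight loss relative to day-0 weight
  r <- rec(c(0, 10:17), weight = c(250, rep(240, 7), 197))
  expect_equal(apply_humane_endpoint(r), 17L)
  # censoring never precedes the first criterion-firing day
  expect_true(is.na(apply_humane_endpoint(rec(10:17))))
})

test_that("a sustained onset always implies incidence", {
  withr::with_seed(19, {
    for (i in 1:200) {
      n <- sample(3:18, 1)
      days <- sort(sample(0:17, n))
      values <- round(runif(n, 0, 10), 1)
      onset <- detect_onset(days, values, 5)
      if (!is.na(onset)) expect_true(call_incidence(days, values, 5))
    }
  })
})

test_that("animal_outcomes assembles censored per-metric calls", {
  study <- tiny_cohort(seed = 21, n = 3)
  feats <- daily_features(study$traces)
  d <- dai_series(feats, baseline_feature(feats))
  out <- animal_outcomes(d, study$clinical)
  expect_setequal(unique(out$metric), c("dai", "joint_size", "arthritis_score"))
  expect_equal(nrow(out), 6 * 3)
  # controls are never arthritic; induced animals always are (by DAI)
  grp <- study$animals$group[match(out$animal_id, study$animals$animal_id)]
  expect_true(all(!out$arthritic[grp == "Control"]))
  expect_true(all(out$arthritic[out$metric == "dai" & grp == "CIA"]))
  # onset, when present, lies at or before any censor day
  has <- !is.na(out$onset_day) & !is.na(out$censor_day)
  expect_true(all(out$onset_day[has] <= out$censor_day[has]))
})
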