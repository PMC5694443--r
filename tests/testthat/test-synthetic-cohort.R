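test_that("latent severity is a delayed, non-decreasing ramp bounded by the endpoint", {
  s <- latent_severity(-3:17, onset_day = 13, endpoint_severity = 0.8)
  expect_true(all(s >= 0 & s <= 0.8))
  expect_true(all(diff(s) >= 0))
  expect_equal(s[match(9, -3:17)], 0)          # before the subclinical ramp
  expect_equal(s[match(14, -3:17)], 0.8)       # plateau reached
  expect_equal(latent_severity(-3:17, NA, 0.9), rep(0, 21))
})

test_that("noise-free traces hit their closed-form dark and light means exactly", {
  cfg0 <- sim_config(baseline_dark_speed_sd = 0)
  st0 <- latent_state("a", cfg0, NA, 0)
  tr <- simulate_trace(st0, cfg0)
  phase <- assign_study_day(tr$timestamp, study_calendar())
  expect_equal(unique(tr$speed_mm_s[phase$dark]), 22.0)
  expect_equal(unique(tr$speed_mm_s[!phase$dark]), 22.0 * 0.3)

  # forced arithmetic: full severity at day 17 under a 43% max reduction
  cfg43 <- sim_config(baseline_dark_speed_sd = 0, max_activity_reduction = 0.43)
  st1 <- latent_state("b", cfg43, 14, 1)   # s(17) = 1
  tr1 <- simulate_trace(st1, cfg43)
  ph1 <- assign_study_day(tr1$timestamp, study_calendar())
  d17 <- ph1$dark & ph1$study_day == 17
  expect_equal(mean(tr1$speed_mm_s[d17]), 22.0 * (1 - 0.43), tolerance = 1e-12)
})

test_that("stochastic dark-cycle means match the analytic expectation within 3 SE", {
  cfg <- sim_config(seed = 7)
  withr::with_seed(7, {
    st <- latent_state("a", cfg, 13, 1)
    tr <- simulate_trace(st, cfg)
  })
  ph <- assign_study_day(tr$timestamp, study_calendar())
  s17 <- latent_severity(17, 13, 1)
  expected <- 22.0 * (1 - 0.45 * s17)
  d17 <- tr$speed_mm_s[ph$dark & ph$study_day == 17]
  se <- (2.4 / 22.0) * expected / sqrt(length(d17))
  expect_lt(abs(mean(d17) - expected), 3 * se)
})

test_that("noise-free measurements equal their closed forms", {
  cfg0 <- sim_config(joint_noise_in = 0, score_noise = 0, histo_noise = 0,
                     weight_noise_g = 0)
  healthy <- simulate_measurements(latent_state("a", cfg0, NA, 0), cfg0)
  w <- tidyr::pivot_wider(healthy$clinical, names_from = metric,
                          values_from = value)
  expect_equal(unique(w$joint_left_in), 0.22)
  expect_equal(unique(w$joint_right_in), 0.22)
  expect_true(all(w$paw_score_left == 0 & w$paw_score_right == 0))
  expect_equal(sum(healthy$histopath[, 3:7]), 0)

  sick <- simulate_measurements(latent_state("b", cfg0, 14, 1), cfg0)  # s(17) = 1
  ws <- tidyr::pivot_wider(sick$clinical, names_from = metric,
                           values_from = value)
  expect_equal(ws$joint_left_in[ws$study_day == 17] -
                 ws$joint_left_in[ws$study_day == 0], 0.12)
  expect_equal(ws$paw_score_left[ws$study_day == 17], 4)
})

test_that("simulated induced cohorts land inside the printed joint-size envelope", {
  study <- simulate_cohort(sim_config(seed = 1),
                           list(group_spec("CIA", 9)))
  w <- tidyr::pivot_wider(study$clinical, names_from = metric,
                          values_from = value)
  delta <- vapply(split(w, w$animal_id), function(a) {
    jt <- pmax(a$joint_left_in, a$joint_right_in)
    jt[a$study_day == 17] - jt[a$study_day == 0]
  }, numeric(1))
  expect_gte(mean(delta), 0.07)
  expect_lte(mean(delta), 0.13)
})

test_that("cohorts conserve counts, are seed-deterministic, and respect group specs", {
  study <- tiny_cohort(seed = 3, n = 4)
  expect_equal(nrow(study$animals), 8)
  expect_equal(length(unique(study$traces$animal_id)), 8)
  expect_true(all(study$animals$endpoint_severity_true[!study$animals$induced] == 0))

  again <- tiny_cohort(seed = 3, n = 4)
  expect_identical(study$traces, again$traces)
  expect_identical(study$clinical, again$clinical)
  expect_identical(study$histopath, again$histopath)

  expect_error(simulate_cohort(sim_config(), list()), class = "daindex_config_error")
  expect_error(simulate_cohort(sim_config(),
                               list(group_spec("A", 2), group_spec("A", 2))),
               class = "daindex_validation_error")
})

test_that("a fully protective treatment is indistinguishable from control", {
  study <- simulate_cohort(
    sim_config(seed = 11),
    list(group_spec("Control", 8, induced = FALSE),
         group_spec("Treated", 8, induced = TRUE, treatment_effect = 0)))
  expect_true(all(study$animals$endpoint_severity_true == 0))
  w <- tidyr::pivot_wider(study$clinical, names_from = metric,
                          values_from = value)
  delta <- vapply(split(w, w$animal_id), function(a) {
    jt <- pmax(a$joint_left_in, a$joint_right_in)
    jt[a$study_day == 17] - jt[a$study_day == 0]
  }, numeric(1))
  grp <- study$animals$group[match(names(delta), study$animals$animal_id)]
  tt <- t.test(delta[grp == "Treated"], delta[grp == "Control"])
  expect_gt(tt$p.value, 1e-3)
})

test_that("default induced cohorts lose 35-50% of dark-cycle activity by endpoint", {
  study <- simulate_cohort(sim_config(seed = 5), list(group_spec("CIA", 6)))
  red <- vapply(split(study$traces, study$traces$animal_id), function(tr) {
    base <- mean_night_motion(tr, -3:-1)
    endp <- mean_night_motion(tr, 16:17)
    (base - endp) / base
  }, numeric(1))
  expect_gte(mean(red), 0.35)
  expect_lte(mean(red), 0.50)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(max_activity_reduction = 1), class = "daindex_config_error")
  expect_error(sim_config(joint_noise_in = -1), class = "daindex_config_error")
  expect_error(sim_config(onset_day_mean = 40), class = "daindex_config_error")
  expect_error(light_schedule("06:00", "06:00"), class = "daindex_config_error")
})
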