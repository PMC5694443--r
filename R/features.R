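#' Nearest-rank sample quantile
#'
#' The percentile rule used for the daily salient feature: the value at
#' sorted rank `ceiling(p * n)`.  Chosen over interpolating definitions
#' because it is reproducible across implementations and always returns an
#' observed sample value.
#'
#' @param x Numeric vector (finite, non-empty).
#' @param p Probability in (0, 1].
#' @return The nearest-rank `p`-quantile of `x`.
#' @examples
#' nearest_rank_quantile(1:720, 0.99)  # 713
#' @export
nearest_rank_quantile <- function(x, p) {
  if (length(x) == 0) stop_domain("cannot take a quantile of an empty vector")
  if (p <= 0 || p > 1) stop_domain("p must be in (0, 1]")
  sort(x)[max(1L, ceiling(p * length(x)))]
}

feature_fun <- function(method) {
  switch(method,
         q99 = function(x) nearest_rank_quantile(x, 0.99),
         max = function(x) max(x),
         mean = function(x) mean(x),
         stop_config("unknown feature method '%s' (use q99, max or mean)", method))
}

validate_trace <- function(trace) {
  req <- c("animal_id", "timestamp", "speed_mm_s")
  if (!all(req %in% names(trace))) {
    stop_validation("trace must have columns %s", paste(req, collapse = ", "))
  }
  if (nrow(trace) == 0) stop_domain("trace is empty")
  if (any(!is.finite(trace$speed_mm_s)) || any(trace$speed_mm_s < 0)) {
    stop_validation("speeds must be finite and >= 0")
  }
  invisible(trace)
}

#' Daily salient activity feature for one study day
#'
#' Summarises the dark-cycle speed samples of one night into a single value
#' (default: the 99th percentile of per-minute speeds, a robust "maximum
#' speed of motion during the dark cycle").  Coverage is the fraction of
#' expected dark-cycle samples actually present; nights with coverage below
#' `min_coverage` yield a missing value rather than a biased one.
#'
#' @param trace Activity tibble `(animal_id, timestamp, speed_mm_s)` for one
#'   animal.
#' @param day Integer study day.
#' @param calendar A [study_calendar()].
#' @param schedule A [light_schedule()].
#' @param method One of `"q99"`, `"max"`, `"mean"`.
#' @param min_coverage Minimum coverage for a usable value (default 0.5).
#' @param sample_period Nominal seconds between samples, used for the
#'   expected dark-cycle sample count.
#' @return One-row tibble `(animal_id, study_day, value, coverage)`.
#' @export
daily_salient_feature <- function(trace, day, calendar = study_calendar(),
                                  schedule = light_schedule(),
                                  method = "q99", min_coverage = 0.5,
                                  sample_period = 60) {
  validate_trace(trace)
  out <- daily_features(trace, calendar, schedule, method = method,
                        min_coverage = min_coverage,
                        sample_period = sample_period)
  res <- out[out$study_day == day, ]
  if (nrow(res) == 0) {
    res <- tibble::tibble(animal_id = trace$animal_id[1],
                          study_day = as.integer(day),
                          value = NA_real_, coverage = 0)
  }
  res
}

#' Daily salient features for all animals and days
#'
#' Vectorised form of [daily_salient_feature()]: one row per animal per
#' study day from the calendar's first to final day, with `NA` values where
#' coverage falls below `min_coverage`.
#'
#' @inheritParams daily_salient_feature
#' @param traces Activity tibble for one or more animals.
#' @return Tibble `(animal_id, study_day, value, coverage)`.
#' @export
daily_features <- function(traces, calendar = study_calendar(),
                           schedule = light_schedule(), method = "q99",
                           min_coverage = 0.5, sample_period = 60) {
  validate_trace(traces)
  f <- feature_fun(method)
  expected_n <- dark_minutes(schedule) * 60 / sample_period
  phase <- assign_study_day(traces$timestamp, calendar, schedule)
  dark <- traces[phase$dark, c("animal_id", "speed_mm_s")]
  dark$study_day <- phase$study_day[phase$dark]

  obs <- dark |>
    dplyr::group_by(.data$animal_id, .data$study_day) |>
    dplyr::summarise(value = f(.data$speed_mm_s),
                     coverage = pmin(1, dplyr::n() / expected_n),
                     .groups = "drop")

  grid <- tidyr::expand_grid(
    animal_id = unique(traces$animal_id),
    study_day = seq(calendar$first_day, calendar$final_day))
  out <- dplyr::left_join(grid, obs, by = c("animal_id", "study_day"))
  out$coverage[is.na(out$coverage)] <- 0
  out$value[out$coverage < min_coverage] <- NA_real_
  out
}

#' Per-animal baseline activity feature
#'
#' The baseline is the arithmetic mean of the non-missing daily features
#' over the baseline window (study days -2 to 5 by default), always
#' excluding induction day 0.  Animals with fewer than `min_baseline_days`
#' usable days are excluded with a warning: their DAI would be normalised
#' against an unstable denominator.
#'
#' @param features Tibble from [daily_features()].
#' @param calendar A [study_calendar()].
#' @param min_baseline_days Minimum usable window days (default 3).
#' @return Tibble `(animal_id, baseline_value, n_days_used)`.
#' @export
baseline_feature <- function(features, calendar = study_calendar(),
                             min_baseline_days = 3L) {
  win <- baseline_days(calendar)
  out <- features |>
    dplyr::filter(.data$study_day %in% win, !is.na(.data$value)) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(baseline_value = mean(.data$value),
                     n_days_used = dplyr::n(), .groups = "drop")
  short <- union(setdiff(unique(features$animal_id), out$animal_id),
                 out$animal_id[out$n_days_used < min_baseline_days])
  if (length(short) > 0) {
    warning(sprintf("excluding %d animal(s) with < %d usable baseline days: %s",
                    length(short), min_baseline_days,
                    paste(short, collapse = ", ")), call. = FALSE)
    out <- out[!out$animal_id %in% short, ]
  }
  out
}

#' Digital Arthritis Index from a daily feature and a baseline
#'
#' `DAI = max(0, K * (1 - value / baseline))`: zero while the animal moves
#' at or above its own baseline, rising towards `K` as dark-cycle activity
#' collapses.  With the default `K = 20` the arthritis threshold of 5
#' corresponds to a 25% activity reduction, and a 43-48% endpoint reduction
#' maps to DAI ~ 9-10, the scale seen in diseased vehicle animals.
#'
#' @param value Daily feature value(s), mm/s (NA propagates).
#' @param baseline Positive baseline feature value(s), mm/s.
#' @param K Scale factor (default 20).
#' @return DAI value(s), unitless, `>= 0`.
#' @examples
#' compute_dai(11, 22)        # 50% reduction -> 10
#' compute_dai(22, 22)        # at baseline -> 0
#' @export
compute_dai <- function(value, baseline, K = 20) {
  if (any(!is.na(baseline) & baseline <= 0)) {
    stop_domain("baseline must be > 0")
  }
  pmax(0, K * (1 - value / baseline))
}

#' Per-animal, per-day DAI series
#'
#' Joins daily features with per-animal baselines and applies
#' [compute_dai()].  Days with missing features yield missing DAI values
#' (never zero); animals without a baseline are dropped.
#'
#' @param features Tibble from [daily_features()].
#' @param baselines Tibble from [baseline_feature()].
#' @param K Scale factor passed to [compute_dai()].
#' @return Tibble `(animal_id, study_day, dai, coverage)`.
#' @export
dai_series <- function(features, baselines, K = 20) {
  out <- dplyr::inner_join(features, baselines, by = "animal_id")
  out$dai <- compute_dai(out$value, out$baseline_value, K)
  out[, c("animal_id", "study_day", "dai", "coverage")]
}

#' Mean dark-cycle motion over a set of study days
#'
#' Pools all dark-cycle speed samples of the listed days and averages them,
#' the summary used to report average nightly motion (e.g. ~22 mm/s at
#' baseline in healthy rats).
#'
#' @param trace Activity tibble for one animal.
#' @param days Integer study days to pool.
#' @param calendar A [study_calendar()].
#' @param schedule A [light_schedule()].
#' @return Mean speed in mm/s, or `NA` (with a warning) if no dark-cycle
#'   samples fall in `days`.
#' @export
mean_night_motion <- function(trace, days, calendar = study_calendar(),
                              schedule = light_schedule()) {
  validate_trace(trace)
  phase <- assign_study_day(trace$timestamp, calendar, schedule)
  keep <- phase$dark & phase$study_day %in% days
  if (!any(keep)) {
    warning("no dark-cycle samples in the requested days", call. = FALSE)
    return(NA_real_)
  }
  mean(trace$speed_mm_s[keep])
}

#' Percent decrease between two activity levels
#'
#' `100 * (before - after) / before`, rounded to the nearest integer
#' percent for reporting (halves away from zero).
#'
#' @param before Reference level (must be > 0).
#' @param after Later level.
#' @return Integer percent decrease (negative if activity increased).
#' @examples
#' percent_decrease(21.7, 18.6)  # 14
#' @export
percent_decrease <- function(before, after) {
  if (any(before <= 0)) stop_domain("'before' must be > 0")
  round_half_up(100 * (before - after) / before)
}
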