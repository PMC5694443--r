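#' Light-dark schedule of the vivarium
#'
#' Rats are housed under a 12-h light-dark cycle (default lights on 06:00,
#' lights off 18:00, local study time).  Activity features use only the dark
#' cycle, when rats are most active.  The dark period that begins at
#' `lights_off` on the calendar date of study day `d` is attributed entirely
#' to study day `d`, even though it spans midnight into day `d + 1`: each
#' dosing day is paired with the following night's behaviour.
#'
#' @param lights_on,lights_off Clock times `"HH:MM"`.  Only schedules with
#'   `lights_on` earlier than `lights_off` are supported (the dark period
#'   wraps midnight).
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule()
#' @export
light_schedule <- function(lights_on = "06:00", lights_off = "18:00") {
  on <- parse_clock(lights_on)
  off <- parse_clock(lights_off)
  if (isTRUE(all.equal(on, off))) {
    stop_config("lights_on and lights_off must differ (got %s for both)", lights_on)
  }
  if (on > off) {
    stop_config("schedules with lights_off before lights_on are not supported")
  }
  structure(list(lights_on = on, lights_off = off), class = "light_schedule")
}

# "HH:MM" -> fractional hours
parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3) stop_config("clock time must be 'HH:MM', got '%s'", x)
  h <- as.numeric(m[2]); mi <- as.numeric(m[3])
  if (h >= 24 || mi >= 60) stop_config("invalid clock time '%s'", x)
  h + mi / 60
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> lights on %05.2fh, off %05.2fh (dark %g min)\n",
              x$lights_on, x$lights_off, dark_minutes(x)))
  invisible(x)
}

dark_minutes <- function(schedule) {
  (24 - (schedule$lights_off - schedule$lights_on)) * 60
}

light_minutes <- function(schedule) {
  (schedule$lights_off - schedule$lights_on) * 60
}

#' Study calendar for a CIA experiment
#'
#' Anchors study days to calendar dates.  Day 0 is the collagen induction
#' day, the booster injection falls on day 7, dosing starts on day 9, and
#' the study ends on day 17.  The DAI baseline window is study days -2 to 5
#' with induction day 0 removed.
#'
#' @param induction_date `Date` of study day 0.  Timestamps are interpreted
#'   in local study time; the default date is arbitrary.
#' @param first_day First acclimation/baseline day (default -3).
#' @param booster_day,dosing_start_day,final_day Study-day milestones.
#' @param baseline_window Integer range `c(first, last)` of the baseline
#'   normalisation window; day 0 is always excluded.
#' @return An object of class `study_calendar`.
#' @examples
#' study_calendar()
#' @export
study_calendar <- function(induction_date = as.Date("2023-01-16"),
                           first_day = -3L,
                           booster_day = 7L,
                           dosing_start_day = 9L,
                           final_day = 17L,
                           baseline_window = c(-2L, 5L)) {
  induction_date <- as.Date(induction_date)
  first_day <- as.integer(first_day)
  final_day <- as.integer(final_day)
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) != 2 || baseline_window[1] > baseline_window[2]) {
    stop_config("baseline_window must be c(first, last) with first <= last")
  }
  if (baseline_window[1] < first_day || baseline_window[2] > final_day) {
    stop_config("baseline_window must lie within the study range [%d, %d]",
                first_day, final_day)
  }
  if (final_day <= dosing_start_day) {
    stop_config("final_day must be after dosing_start_day")
  }
  structure(list(induction_date = induction_date,
                 first_day = first_day,
                 booster_day = as.integer(booster_day),
                 dosing_start_day = as.integer(dosing_start_day),
                 final_day = final_day,
                 baseline_window = baseline_window),
            class = "study_calendar")
}

#' @export
print.study_calendar <- function(x, ...) {
  cat(sprintf(paste0("<study_calendar> induction %s (day 0), days %d..%d, ",
                     "booster day %d, dosing from day %d, baseline %d..%d (excl. 0)\n"),
              format(x$induction_date), x$first_day, x$final_day,
              x$booster_day, x$dosing_start_day,
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

baseline_days <- function(calendar) {
  setdiff(seq(calendar$baseline_window[1], calendar$baseline_window[2]), 0L)
}

study_day_date <- function(calendar, day) calendar$induction_date + day

#' Assign timestamps to study days and light phases
#'
#' Maps each timestamp to its study day under the night-attribution
#' convention: dark-cycle samples recorded after midnight belong to the
#' night that began at `lights_off` on the previous calendar day.
#' Light-cycle samples belong to their own calendar day and are flagged.
#'
#' @param timestamp `POSIXct` vector in local study time (stored as UTC).
#' @param calendar A [study_calendar()].
#' @param schedule A [light_schedule()].
#' @return A tibble with columns `study_day` (integer) and `dark` (logical).
#' @examples
#' cal <- study_calendar()
#' ts <- as.POSIXct("2023-01-19 23:00:00", tz = "UTC")  # day 3, 23:00
#' assign_study_day(ts, cal, light_schedule())
#' @export
assign_study_day <- function(timestamp, calendar, schedule = light_schedule()) {
  stopifnot(inherits(timestamp, "POSIXct"))
  secs <- as.numeric(timestamp)
  date <- as.Date(floor(secs / 86400), origin = "1970-01-01")
  tod <- (secs %% 86400) / 3600
  day <- as.integer(date - calendar$induction_date)
  dark <- tod >= schedule$lights_off | tod < schedule$lights_on
  # post-midnight dark samples belong to the previous night's study day
  day <- day - as.integer(tod < schedule$lights_on)
  if (any(day < calendar$first_day)) {
    stop_domain("timestamps before first study day %d", calendar$first_day)
  }
  tibble::tibble(study_day = day, dark = dark)
}
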