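# Fixtures are built in code: small hand-crafted traces with known
# dark-cycle content, under the default calendar (induction 2023-01-16)
# and 06:00-18:00 light schedule.

default_cal <- study_calendar()
default_sched <- light_schedule()

# timestamps of the night attributed to `day`: 18:00 of day's date to
# 05:59 next morning, one per minute
night_timestamps <- function(day, cal = default_cal) {
  start <- as.POSIXct(cal$induction_date, tz = "UTC") + day * 86400 + 18 * 3600
  start + seq(0, by = 60, length.out = 720)
}

day_timestamps <- function(day, cal = default_cal) {
  start <- as.POSIXct(cal$induction_date, tz = "UTC") + day * 86400 + 6 * 3600
  start + seq(0, by = 60, length.out = 720)
}

# trace holding given per-minute dark speeds for each named study day;
# speeds recycled to 720 samples per night
make_night_trace <- function(id, day_speeds, cal = default_cal) {
  rows <- lapply(names(day_speeds), function(d) {
    day <- as.integer(d)
    tibble::tibble(animal_id = id,
                   timestamp = night_timestamps(day, cal),
                   speed_mm_s = rep_len(day_speeds[[d]], 720))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$timestamp), ]
}

# constant-speed nights over several days
constant_night_trace <- function(id, days, speed, cal = default_cal) {
  make_night_trace(id, stats::setNames(as.list(rep(speed, length(days))),
                                       as.character(days)), cal)
}

# small simulated cohorts are reused across test files
tiny_cohort <- function(seed = 3, n = 2) {
  simulate_cohort(sim_config(seed = seed),
                  list(group_spec("CIA", n),
                       group_spec("Control", n, induced = FALSE)))
}
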