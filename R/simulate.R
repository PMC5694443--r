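#' Simulator configuration
#'
#' Defaults are calibrated to a standard rat collagen-induced arthritis
#' (CIA) study monitored by continuous home-cage activity sensing: healthy
#' animals move at about 22 mm/s on average during the dark cycle with an
#' across-sample spread of about 2.4 mm/s, disease onset clusters around
#' study day 13, and fully arthritic animals lose up to ~45% of their
#' dark-cycle activity.  Speed noise has constant coefficient of variation
#' (spread scales with the mean), so relative activity reductions survive
#' quantile-based feature extraction.
#'
#' @param n_per_group Animals per group (default 9).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `(config, groups, seed)`.
#' @param baseline_dark_speed_mean,baseline_dark_speed_sd Per-minute dark-cycle
#'   speed mean and SD at baseline, mm/s.
#' @param light_speed_fraction Light-cycle mean speed as a fraction of the
#'   dark-cycle mean (rats are largely inactive in the light).
#' @param onset_day_mean,onset_day_sd Clinical onset day distribution for
#'   induced animals (the day measures are expected to cross their
#'   thresholds).
#' @param max_activity_reduction Fractional dark-cycle activity loss at full
#'   latent severity, in `[0, 1)`.
#' @param endpoint_severity_mean,endpoint_severity_sd Distribution of the
#'   per-animal latent endpoint severity before truncation to `[0, 1]`.
#' @param ramp_days Days over which latent severity ramps from 0 to the
#'   endpoint value.
#' @param onset_lead_days Days by which the subclinical latent ramp precedes
#'   the nominal clinical onset day.
#' @param joint_baseline_in,joint_gain_in Ankle joint size at baseline and
#'   its gain at full severity, inches.
#' @param joint_noise_in Caliper measurement SD, inches.
#' @param score_noise SD of the latent noise added before discretising paw
#'   scores.
#' @param histo_noise SD of the noise added to each histopathology subscore.
#' @param weight_baseline_g,weight_loss_max,weight_noise_g Body-weight model:
#'   baseline grams, maximum fractional loss at full severity, and
#'   measurement SD.
#' @param sample_period Seconds between speed samples (default one per
#'   minute).
#' @param study_days Integer vector of simulated study days.
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(n_per_group = 4, seed = 1)
#' @export
sim_config <- function(n_per_group = 9L,
                       seed = 1L,
                       baseline_dark_speed_mean = 22.0,
                       baseline_dark_speed_sd = 2.4,
                       light_speed_fraction = 0.3,
                       onset_day_mean = 13,
                       onset_day_sd = 1.0,
                       max_activity_reduction = 0.45,
                       endpoint_severity_mean = 0.95,
                       endpoint_severity_sd = 0.1,
                       ramp_days = 4L,
                       onset_lead_days = 3L,
                       joint_baseline_in = 0.22,
                       joint_gain_in = 0.12,
                       joint_noise_in = 0.006,
                       score_noise = 0.5,
                       histo_noise = 0.4,
                       weight_baseline_g = 250,
                       weight_loss_max = 0.08,
                       weight_noise_g = 2,
                       sample_period = 60,
                       study_days = -3:17) {
  cfg <- list(n_per_group = as.integer(n_per_group), seed = as.integer(seed),
              baseline_dark_speed_mean = baseline_dark_speed_mean,
              baseline_dark_speed_sd = baseline_dark_speed_sd,
              light_speed_fraction = light_speed_fraction,
              onset_day_mean = onset_day_mean, onset_day_sd = onset_day_sd,
              max_activity_reduction = max_activity_reduction,
              endpoint_severity_mean = endpoint_severity_mean,
              endpoint_severity_sd = endpoint_severity_sd,
              ramp_days = as.integer(ramp_days),
              onset_lead_days = as.integer(onset_lead_days),
              joint_baseline_in = joint_baseline_in,
              joint_gain_in = joint_gain_in,
              joint_noise_in = joint_noise_in,
              score_noise = score_noise, histo_noise = histo_noise,
              weight_baseline_g = weight_baseline_g,
              weight_loss_max = weight_loss_max,
              weight_noise_g = weight_noise_g,
              sample_period = sample_period,
              study_days = as.integer(study_days))
  disp <- c("baseline_dark_speed_sd", "onset_day_sd", "endpoint_severity_sd",
            "joint_noise_in", "score_noise", "histo_noise", "weight_noise_g")
  for (nm in disp) {
    if (cfg[[nm]] < 0) stop_config("%s must be >= 0", nm)
  }
  if (cfg$max_activity_reduction < 0 || cfg$max_activity_reduction >= 1) {
    stop_config("max_activity_reduction must be in [0, 1)")
  }
  if (cfg$light_speed_fraction <= 0 || cfg$light_speed_fraction >= 1) {
    stop_config("light_speed_fraction must be in (0, 1)")
  }
  if (cfg$onset_day_mean < min(cfg$study_days) ||
      cfg$onset_day_mean > max(cfg$study_days)) {
    stop_config("onset_day_mean must lie within study_days")
  }
  if (cfg$sample_period <= 0) stop_config("sample_period must be > 0")
  structure(cfg, class = "sim_config")
}

# relative contribution of each histopathology subscore to endpoint disease;
# inflammation dominates in CIA, periosteal bone formation is sparse
histo_loadings <- c(inflammation = 1.0, pannus = 0.35, cartilage_damage = 0.40,
                    bone_resorption = 0.35, periosteal_bone = 0.20)

#' Latent per-day disease severity
#'
#' Severity is 0 before disease, ramps piecewise-linearly to the animal's
#' endpoint severity over `ramp_days`, and stays flat afterwards.  The ramp
#' is positioned `onset_lead` days before the nominal clinical `onset_day`
#' so that measured metrics cross their thresholds at about `onset_day`,
#' mirroring the subclinical build-up of joint pathology.
#'
#' @param days Integer study days.
#' @param onset_day Clinical onset day, or `NA` for non-diseased animals.
#' @param endpoint_severity Severity plateau in `[0, 1]`.
#' @param ramp_days,onset_lead Ramp length and subclinical lead, days.
#' @return Numeric vector of severities in `[0, 1]`, non-decreasing in `days`.
#' @examples
#' latent_severity(-3:17, onset_day = 13, endpoint_severity = 1)
#' @export
latent_severity <- function(days, onset_day, endpoint_severity,
                            ramp_days = 4L, onset_lead = 3L) {
  stopifnot(endpoint_severity >= 0, endpoint_severity <= 1)
  if (is.na(onset_day) || endpoint_severity == 0) return(rep(0, length(days)))
  ramp_start <- onset_day - onset_lead
  endpoint_severity * clamp((days - ramp_start) / ramp_days, 0, 1)
}

#' Latent disease state of one animal
#'
#' @param animal_id Character id.
#' @param config A [sim_config()].
#' @param onset_day Clinical onset day or `NA` (healthy).
#' @param endpoint_severity Endpoint latent severity in `[0, 1]`.
#' @return A list of class `latent_state` with the per-day severity `s`.
#' @examples
#' latent_state("r1", sim_config(), onset_day = 13, endpoint_severity = 0.9)
#' @export
latent_state <- function(animal_id, config, onset_day, endpoint_severity) {
  days <- config$study_days
  if (!is.na(onset_day) && !(onset_day %in% days)) {
    stop_config("onset_day %s outside simulated study days", onset_day)
  }
  s <- latent_severity(days, onset_day, endpoint_severity,
                       config$ramp_days, config$onset_lead_days)
  structure(list(animal_id = animal_id, days = days, s = s,
                 onset_day = onset_day, endpoint_severity = endpoint_severity),
            class = "latent_state")
}

# truncated-at-zero normal draws via inverse CDF (exact, vectorised)
rtrunc0 <- function(n, mean, sd) {
  if (all(sd == 0)) return(rep_len(mean, n))
  lo <- pnorm(0, mean, sd)
  qnorm(runif(n, lo, 1), mean, sd)
}

#' Simulate a continuous activity trace
#'
#' Generates one speed sample per `sample_period` over every simulated study
#' day.  The expected dark-cycle speed on day `d` is
#' `baseline_dark_speed_mean * (1 - max_activity_reduction * s(d))`; the
#' light-cycle mean is that times `light_speed_fraction`.  Noise is
#' truncated-Gaussian at 0 with SD proportional to the local mean (constant
#' CV fixed by the baseline mean and SD).
#'
#' @param state A [latent_state()].
#' @param config A [sim_config()].
#' @param schedule A [light_schedule()].
#' @param calendar A [study_calendar()].
#' @return A tibble `(animal_id, timestamp, speed_mm_s)` with strictly
#'   increasing timestamps.
#' @examples
#' st <- latent_state("r1", sim_config(study_days = 0:1), NA, 0)
#' tr <- simulate_trace(st, sim_config(study_days = 0:1))
#' @export
simulate_trace <- function(state, config, schedule = light_schedule(),
                           calendar = study_calendar()) {
  stopifnot(inherits(state, "latent_state"), inherits(config, "sim_config"))
  if (!all(state$days %in% config$study_days)) {
    stop_config("state days must be a subset of config study_days")
  }
  sp <- config$sample_period
  n_light <- as.integer(light_minutes(schedule) * 60 / sp)
  n_dark <- as.integer(dark_minutes(schedule) * 60 / sp)
  cv <- config$baseline_dark_speed_sd / config$baseline_dark_speed_mean

  day0 <- as.numeric(as.POSIXct(calendar$induction_date, tz = "UTC"))
  light_off <- schedule$lights_on * 3600 + seq(0, by = sp, length.out = n_light)
  dark_off <- schedule$lights_off * 3600 + seq(0, by = sp, length.out = n_dark)

  per_day <- lapply(seq_along(state$days), function(i) {
    d <- state$days[i]
    dark_mean <- config$baseline_dark_speed_mean *
      (1 - config$max_activity_reduction * state$s[i])
    light_mean <- dark_mean * config$light_speed_fraction
    base <- day0 + d * 86400
    tibble::tibble(
      timestamp = .POSIXct(c(base + light_off, base + dark_off), tz = "UTC"),
      speed_mm_s = c(rtrunc0(n_light, light_mean, cv * light_mean),
                     rtrunc0(n_dark, dark_mean, cv * dark_mean)))
  })
  out <- dplyr::bind_rows(per_day)
  out$animal_id <- state$animal_id
  out[, c("animal_id", "timestamp", "speed_mm_s")]
}

#' Simulate longitudinal clinical measurements and endpoint histopathology
#'
#' Daily (day 0 to the last simulated day) hind-limb joint sizes, per-paw
#' arthritis scores, and body weight, plus five endpoint histopathology
#' subscores per ankle.  Joint size grows linearly in latent severity; paw
#' scores are the severity discretised onto the 0-4 rubric; subscores grow
#' with endpoint severity weighted by how strongly each pathology loads on
#' CIA disease (inflammation heaviest).  All values are clamped to their
#' physical or rubric bounds.
#'
#' @inheritParams simulate_trace
#' @return A list with `clinical` (long tibble: `animal_id, study_day,
#'   metric, value`) and `histopath` (one row per side with the five
#'   subscores).
#' @examples
#' st <- latent_state("r1", sim_config(), 13, 0.9)
#' m <- simulate_measurements(st, sim_config())
#' @export
simulate_measurements <- function(state, config) {
  stopifnot(inherits(state, "latent_state"), inherits(config, "sim_config"))
  keep <- state$days >= 0
  days <- state$days[keep]
  s <- state$s[keep]
  n <- length(days)

  joint <- function() clamp(config$joint_baseline_in + config$joint_gain_in * s +
                              rnorm(n, 0, config$joint_noise_in), 0, Inf)
  paw <- function() as.integer(clamp(round(4 * s + rnorm(n, 0, config$score_noise)), 0, 4))
  jl <- joint(); jr <- joint()
  pl <- paw(); pr <- paw()
  bw <- config$weight_baseline_g * (1 - config$weight_loss_max * s) +
    rnorm(n, 0, config$weight_noise_g)

  clinical <- tibble::tibble(
    animal_id = state$animal_id,
    study_day = rep(days, 5),
    metric = rep(c("joint_left_in", "joint_right_in",
                   "paw_score_left", "paw_score_right", "body_weight_g"),
                 each = n),
    value = c(jl, jr, as.numeric(pl), as.numeric(pr), bw))

  e <- state$endpoint_severity
  side_scores <- function(side) {
    sub <- as.integer(clamp(round(5 * histo_loadings * e +
                                    rnorm(5, 0, config$histo_noise)), 0, 5))
    tibble::tibble(animal_id = state$animal_id, side = side,
                   inflammation = sub[1], pannus = sub[2],
                   cartilage_damage = sub[3], bone_resorption = sub[4],
                   periosteal_bone = sub[5])
  }
  list(clinical = clinical,
       histopath = dplyr::bind_rows(side_scores("left"), side_scores("right")))
}

#' Specify a simulated treatment group
#'
#' @param name Group label (e.g. `"CIA_Vehicle"`).
#' @param n Number of animals.
#' @param induced Whether animals receive CIA induction (controls have zero
#'   latent severity throughout).
#' @param treatment_effect Multiplier in `[0, 1]` on latent severity; 1 = no
#'   protection, 0 = full protection.
#' @param compound,dose Optional compound label and dose level
#'   (`"low"`/`"medium"`/`"high"`), carried into ranking outputs.
#' @return A list of class `group_spec`.
#' @examples
#' group_spec("CIA_Vehicle", 9)
#' @export
group_spec <- function(name, n, induced = TRUE, treatment_effect = 1,
                       compound = NA_character_, dose = NA_character_) {
  if (treatment_effect < 0 || treatment_effect > 1) {
    stop_config("treatment_effect must be in [0, 1]")
  }
  structure(list(name = name, n = as.integer(n), induced = isTRUE(induced),
                 treatment_effect = treatment_effect,
                 compound = compound, dose = dose),
            class = "group_spec")
}

#' Simulate a full study cohort
#'
#' Draws, per induced animal, a clinical onset day and an endpoint latent
#' severity (attenuated by the group's `treatment_effect`), then simulates
#' the activity trace and all clinical measurements.  Control animals have
#' zero severity throughout.  The result is a deterministic function of the
#' configuration and seed.
#'
#' @param config A [sim_config()].
#' @param groups List of [group_spec()]s.
#' @param calendar A [study_calendar()].
#' @param schedule A [light_schedule()].
#' @return A list of class `dai_study` with elements `animals` (design +
#'   latent truth), `traces`, `clinical`, `histopath`, `config`, `calendar`,
#'   `schedule`.
#' @examples
#' study <- simulate_cohort(sim_config(seed = 3),
#'                          list(group_spec("CIA", 2), group_spec("Control", 2, induced = FALSE)))
#' @export
simulate_cohort <- function(config, groups,
                            calendar = study_calendar(),
                            schedule = light_schedule()) {
  stopifnot(inherits(config, "sim_config"))
  if (length(groups) < 1) stop_config("at least one group is required")
  ids <- unlist(lapply(groups, function(g) {
    sprintf("%s_%02d", g$name, seq_len(g$n))
  }))
  if (anyDuplicated(ids)) {
    stop_validation("duplicate animal ids: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  withr::with_seed(config$seed, {
    animals <- list(); traces <- list(); clin <- list(); histo <- list()
    for (g in groups) {
      for (k in seq_len(g$n)) {
        id <- sprintf("%s_%02d", g$name, k)
        if (g$induced) {
          onset <- as.integer(clamp(
            round(rnorm(1, config$onset_day_mean, config$onset_day_sd)),
            min(config$study_days) + config$onset_lead_days + 1L,
            max(config$study_days)))
          e <- clamp(rnorm(1, config$endpoint_severity_mean,
                           config$endpoint_severity_sd), 0, 1) * g$treatment_effect
        } else {
          onset <- NA_integer_
          e <- 0
        }
        st <- latent_state(id, config, onset, e)
        traces[[id]] <- simulate_trace(st, config, schedule, calendar)
        m <- simulate_measurements(st, config)
        clin[[id]] <- m$clinical
        histo[[id]] <- m$histopath
        animals[[id]] <- tibble::tibble(
          animal_id = id, group = g$name, induced = g$induced,
          treatment_effect = g$treatment_effect,
          compound = g$compound, dose = g$dose,
          onset_day_true = onset, endpoint_severity_true = e)
      }
    }
    structure(list(animals = dplyr::bind_rows(animals),
                   traces = dplyr::bind_rows(traces),
                   clinical = dplyr::bind_rows(clin),
                   histopath = dplyr::bind_rows(histo),
                   config = config, calendar = calendar, schedule = schedule),
              class = "dai_study")
  })
}

#' @export
print.dai_study <- function(x, ...) {
  cat(sprintf("<dai_study> %d animals in %d groups, %d activity samples, days %d..%d\n",
              nrow(x$animals), length(unique(x$animals$group)),
              nrow(x$traces), min(x$config$study_days), max(x$config$study_days)))
  print(dplyr::count(x$animals, .data$group, .data$induced))
  invisible(x)
}
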