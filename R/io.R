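ts_format <- "%Y-%m-%dT%H:%M:%S"

format_ts <- function(ts) format(ts, ts_format, tz = "UTC")

parse_ts <- function(x) {
  out <- as.POSIXct(x, format = ts_format, tz = "UTC")
  bad <- which(is.na(out) & !is.na(x))
  list(ts = out, bad = bad)
}

read_csv_strict <- function(path, col_types) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  # header and row problems are reported below with line numbers; readr's
  # own mismatch warnings would duplicate them
  out <- suppressWarnings(readr::read_csv(path, col_types = col_types,
                                          progress = FALSE))
  expected <- names(col_types$cols)
  if (!identical(names(out), expected)) {
    stop_validation("%s: expected header '%s', found '%s'", path,
                    paste(expected, collapse = ","),
                    paste(names(out), collapse = ","))
  }
  pr <- readr::problems(out)
  if (nrow(pr) > 0) {
    stop_validation("%s: malformed rows at line(s) %s", path,
                    paste(unique(pr$row + 1L), collapse = ", "))
  }
  out
}

#' Read and write activity trace CSVs
#'
#' The trace dialect is `animal_id,timestamp,speed_mm_s` with ISO-8601
#' timestamps in local study time.  Reading validates every row: malformed
#' values are rejected with their line numbers, speeds must be finite and
#' non-negative, and timestamps must be strictly increasing within each
#' animal.
#'
#' @param path CSV file path.
#' @return `read_traces()` returns the trace tibble; `write_traces()`
#'   invisibly returns `path`.
#' @export
read_traces <- function(path) {
  out <- read_csv_strict(path, readr::cols(animal_id = readr::col_character(),
                                           timestamp = readr::col_character(),
                                           speed_mm_s = readr::col_double()))
  if (nrow(out) == 0) {
    warning(sprintf("%s: no data rows", path), call. = FALSE)
    return(tibble::tibble(animal_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          speed_mm_s = double()))
  }
  p <- parse_ts(out$timestamp)
  if (length(p$bad) > 0) {
    stop_validation("%s: unparseable timestamps at line(s) %s", path,
                    paste(p$bad + 1L, collapse = ", "))
  }
  bad_speed <- which(!is.finite(out$speed_mm_s) | out$speed_mm_s < 0)
  if (length(bad_speed) > 0) {
    stop_validation("%s: negative or non-finite speeds at line(s) %s", path,
                    paste(bad_speed + 1L, collapse = ", "))
  }
  out$timestamp <- p$ts
  non_mono <- out |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(ok = all(diff(as.numeric(.data$timestamp)) > 0),
                     .groups = "drop")
  if (any(!non_mono$ok)) {
    stop_validation("%s: non-monotone timestamps for animal(s) %s", path,
                    paste(non_mono$animal_id[!non_mono$ok], collapse = ", "))
  }
  out
}

#' @rdname read_traces
#' @param traces Trace tibble `(animal_id, timestamp, speed_mm_s)`.
#' @export
write_traces <- function(traces, path) {
  out <- traces
  out$timestamp <- format_ts(out$timestamp)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write long-format clinical measurement CSVs
#'
#' Dialect: `animal_id,study_day,metric,value` with metrics
#' `joint_left_in`, `joint_right_in`, `paw_score_left`, `paw_score_right`,
#' `body_weight_g`.  Paw scores are validated against the 0-4 rubric on
#' read.
#'
#' @param path CSV file path.
#' @return `read_measurements()` returns the long tibble;
#'   `write_measurements()` invisibly returns `path`.
#' @export
read_measurements <- function(path) {
  out <- read_csv_strict(path, readr::cols(animal_id = readr::col_character(),
                                           study_day = readr::col_integer(),
                                           metric = readr::col_character(),
                                           value = readr::col_double()))
  known <- c("joint_left_in", "joint_right_in", "paw_score_left",
             "paw_score_right", "body_weight_g")
  bad <- setdiff(unique(out$metric), known)
  if (length(bad) > 0) {
    stop_validation("%s: unknown metric(s) %s", path, paste(bad, collapse = ", "))
  }
  check_ordinal(out$value[out$metric %in% c("paw_score_left", "paw_score_right")],
                4L, "paw scores")
  out
}

#' @rdname read_measurements
#' @param measurements Long clinical tibble.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path, progress = FALSE)
  invisible(path)
}

#' Read and write histopathology CSVs
#'
#' Dialect: `animal_id,side,inflammation,pannus,cartilage_damage,
#' bone_resorption,periosteal_bone`, one row per scored ankle, subscores
#' 0-5.
#'
#' @param path CSV file path.
#' @return `read_histopath()` returns the tibble; `write_histopath()`
#'   invisibly returns `path`.
#' @export
read_histopath <- function(path) {
  out <- read_csv_strict(path, readr::cols(animal_id = readr::col_character(),
                                           side = readr::col_character(),
                                           inflammation = readr::col_integer(),
                                           pannus = readr::col_integer(),
                                           cartilage_damage = readr::col_integer(),
                                           bone_resorption = readr::col_integer(),
                                           periosteal_bone = readr::col_integer()))
  for (nm in c("inflammation", "pannus", "cartilage_damage",
               "bone_resorption", "periosteal_bone")) {
    check_ordinal(out[[nm]], 5L, paste(nm, "subscores"))
  }
  out
}

#' @rdname read_histopath
#' @param histopath Histopathology tibble.
#' @export
write_histopath <- function(histopath, path) {
  readr::write_csv(histopath, path, progress = FALSE)
  invisible(path)
}

#' Read a study configuration file
#'
#' YAML configuration holding group assignments, calendar milestones, light
#' schedule, thresholds, feature settings and optional simulator
#' parameters.  Missing thresholds fall back to the defaults (0.25 in / 4 /
#' 5) with a message; missing calendar/schedule/feature fields fall back to
#' package defaults.
#'
#' @param path YAML file path.
#' @return A list of class `study_config` with elements `groups` (list of
#'   [group_spec()]), `calendar`, `schedule`, `thresholds`, `endpoint`,
#'   `feature` (`method`, `K`, `min_coverage`, `min_baseline_days`),
#'   `simulator` ([sim_config()] or `NULL`) and `seed`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  # YAML 1.1 would read a bare `n` key as a boolean; keep y/n as strings
  keep_yn <- list(
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes")) TRUE else x,
    "bool#no" = function(x) if (tolower(x) %in% c("false", "no")) FALSE else x)
  raw <- yaml::read_yaml(path, handlers = keep_yn)

  if (is.null(raw$groups) || length(raw$groups) == 0) {
    stop_validation("config must define at least one group")
  }
  groups <- lapply(raw$groups, function(g) {
    group_spec(name = g$name, n = g$n,
               induced = g$induced %||% TRUE,
               treatment_effect = g$treatment_effect %||% 1,
               compound = g$compound %||% NA_character_,
               dose = g$dose %||% NA_character_)
  })
  if (anyDuplicated(vapply(groups, `[[`, "", "name"))) {
    stop_validation("duplicate group names in config")
  }

  cal_args <- raw$calendar %||% list()
  calendar <- do.call(study_calendar, cal_args)
  sch_args <- raw$schedule %||% list()
  schedule <- do.call(light_schedule, sch_args)

  if (is.null(raw$thresholds)) {
    message("no thresholds in config; using defaults (0.25 in / 4 / 5)")
    thresholds <- threshold_config()
  } else {
    thresholds <- do.call(threshold_config, raw$thresholds)
  }
  endpoint <- do.call(endpoint_rule, raw$endpoint %||% list())

  feat <- raw$feature %||% list()
  feature <- list(method = feat$method %||% "q99",
                  K = feat$K %||% 20,
                  min_coverage = feat$min_coverage %||% 0.5,
                  min_baseline_days = feat$min_baseline_days %||% 3L)
  feature_fun(feature$method)  # fail fast on unknown methods

  seed <- as.integer(raw$seed %||% 1L)
  simulator <- if (!is.null(raw$simulator)) {
    do.call(sim_config, c(raw$simulator, list(seed = seed)))
  }

  structure(list(groups = groups, calendar = calendar, schedule = schedule,
                 thresholds = thresholds, endpoint = endpoint,
                 feature = feature, simulator = simulator, seed = seed),
            class = "study_config")
}

#' Deterministic hash of a configuration
#'
#' Stamped into every pipeline output so artifacts can be traced back to
#' the exact configuration that produced them.
#'
#' @param config Any R object.
#' @return A hash string.
#' @export
config_hash <- function(config) rlang::hash(config)
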