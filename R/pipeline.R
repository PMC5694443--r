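write_output <- function(tbl, path, hash) {
  cat(sprintf("# config_hash: %s\n", hash), readr::format_csv(tbl),
      sep = "", file = path)
  invisible(path)
}

#' Read a pipeline output CSV
#'
#' Pipeline outputs are RFC-4180 CSVs preceded by a single `# config_hash:`
#' comment line; this reader skips it.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_output <- function(path) {
  readr::read_csv(path, comment = "#", progress = FALSE,
                  show_col_types = FALSE)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("[%s] %s", stage, conditionMessage(e)),
                 class = "daindex_stage_error", parent = e)
  })
}

#' Run the full DAI pipeline
#'
#' End-to-end run over a study dataset: daily salient features, per-animal
#' baselines and DAI series, humane-endpoint censoring and per-metric
#' outcomes, group summaries, cross-correlations with histopathology, and
#' (when compound groups are present) compound rankings.  All artifacts are
#' deterministic functions of the inputs and carry the configuration hash;
#' identical reruns are byte-identical.  Any stage failure aborts with a
#' stage-tagged error and removes partial outputs.
#'
#' @param study A `dai_study` (from [simulate_cohort()]) or a list with
#'   elements `traces`, `clinical`, `histopath` (optional), `animals`
#'   (optional: `animal_id`, `group`, `compound`, `dose`).
#' @param out_dir Output directory (created if needed).
#' @param config Optional `study_config` from [read_study_config()];
#'   supplies calendar, schedule, thresholds, endpoint rule and feature
#'   settings.  Defaults are used otherwise.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(study, out_dir, config = NULL) {
  calendar <- config$calendar %||% study$calendar %||% study_calendar()
  schedule <- config$schedule %||% study$schedule %||% light_schedule()
  thresholds <- config$thresholds %||% threshold_config()
  endpoint <- config$endpoint %||% endpoint_rule()
  feature <- config$feature %||% list(method = "q99", K = 20,
                                      min_coverage = 0.5, min_baseline_days = 3L)
  sample_period <- study$config$sample_period %||%
    (config$simulator$sample_period %||% 60)

  hash_input <- list(calendar = calendar, schedule = schedule,
                     thresholds = unclass(thresholds),
                     endpoint = unclass(endpoint), feature = feature,
                     seed = config$seed %||% study$config$seed %||% NA)
  hash <- config_hash(hash_input)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  on_fail_cleanup <- function() unlink(files)

  res <- tryCatch({
    feats <- pipeline_stage("features", daily_features(
      study$traces, calendar, schedule, method = feature$method,
      min_coverage = feature$min_coverage, sample_period = sample_period))
    files["features"] <- write_output(feats, file.path(out_dir, "features.csv"), hash)

    dai <- pipeline_stage("dai", {
      base <- baseline_feature(feats, calendar, feature$min_baseline_days)
      dai_series(feats, base, K = feature$K)
    })
    files["dai"] <- write_output(dai, file.path(out_dir, "dai.csv"), hash)

    outcomes <- pipeline_stage("outcomes", animal_outcomes(
      dai, study$clinical, thresholds, endpoint, calendar))
    if (!is.null(study$animals)) {
      outcomes <- dplyr::left_join(
        outcomes,
        study$animals[, intersect(c("animal_id", "group", "compound", "dose"),
                                  names(study$animals))],
        by = "animal_id")
    } else {
      outcomes$group <- "all"
    }
    files["outcomes"] <- write_output(outcomes, file.path(out_dir, "outcomes.csv"), hash)

    summary_tbl <- pipeline_stage("summarize", summarize_group(outcomes))
    files["group_summary"] <- write_output(
      summary_tbl, file.path(out_dir, "group_summary.csv"), hash)

    correl <- pipeline_stage("correlations", {
      sev <- severity_table(outcomes, study$histopath)
      correlation_table(sev)
    })
    files["correlations"] <- write_output(
      correl, file.path(out_dir, "correlations.csv"), hash)

    ranks <- pipeline_stage("rank", {
      if (!is.null(study$animals) && "compound" %in% names(study$animals) &&
          sum(!is.na(unique(study$animals$compound))) >= 2) {
        compound_rank_table(outcomes, study$histopath)
      } else NULL
    })
    if (!is.null(ranks)) {
      files["ranks"] <- write_output(ranks, file.path(out_dir, "ranks.csv"), hash)
    }

    log_lines <- c(sprintf("config_hash: %s", hash),
                   sprintf("seed: %s", hash_input$seed),
                   sprintf("animals: %d", length(unique(outcomes$animal_id))),
                   sprintf("outputs: %s", paste(basename(files), collapse = ", ")))
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(log_lines, log_path)
    files["log"] <- log_path
    files
  }, error = function(e) {
    on_fail_cleanup()
    rlang::abort(conditionMessage(e), class = "daindex_pipeline_error", parent = e)
  })
  invisible(res)
}

#' Compound rank table from per-animal outcomes
#'
#' Pools animals by compound (all doses combined), computes mean severity
#' per assessment method (DAI, arthritis score, joint-size change, and when
#' histopathology is available the total and inflammation scores), and
#' applies competition ranking within each method via [rank_compounds()].
#'
#' @param outcomes Tibble from [animal_outcomes()] carrying a `compound`
#'   column.
#' @param histopath Optional side-level histopathology tibble.
#' @return Tibble `(compound, method, mean, sd, n, rank)`.
#' @export
compound_rank_table <- function(outcomes, histopath = NULL) {
  if (!"compound" %in% names(outcomes)) {
    stop_validation("outcomes must carry a 'compound' column")
  }
  sev <- severity_table(outcomes, histopath)
  key <- dplyr::distinct(outcomes[!is.na(outcomes$compound),
                                  c("animal_id", "compound")])
  sev <- dplyr::inner_join(sev, key, by = "animal_id")
  methods <- intersect(c("dai", "arthritis_score", "joint_size",
                         "histo_total", "inflammation"), names(sev))
  long <- tidyr::pivot_longer(sev[, c("compound", methods)],
                              dplyr::all_of(methods),
                              names_to = "method", values_to = "value")
  means <- long |>
    dplyr::group_by(.data$compound, .data$method) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
  means$mean[is.nan(means$mean)] <- NA_real_
  rank_compounds(means)
}
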