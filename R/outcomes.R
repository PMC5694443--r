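#' Disease thresholds
#'
#' An animal counts as arthritic when a metric is strictly greater than its
#' threshold: ankle joint size 0.25 inches, total arthritis score 4, DAI 5.
#'
#' @param joint_size_in,arthritis_score,dai Threshold values.
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(joint_size_in = 0.25, arthritis_score = 4, dai = 5) {
  th <- list(joint_size_in = joint_size_in,
             arthritis_score = arthritis_score, dai = dai)
  if (any(unlist(th) <= 0)) stop_config("all thresholds must be > 0")
  structure(th, class = "threshold_config")
}

#' Humane-endpoint censoring rule
#'
#' Animals are euthanised (and their series censored) at the earliest day
#' any criterion fires: rear joint size at or above 0.4 inches, a maximal
#' paw score of 4 sustained for more than 48 h (3 or more consecutive daily
#' observations), or body-weight loss exceeding 20% of baseline.
#'
#' @param joint_limit_in Joint size limit, inches (fires at `>=`).
#' @param max_paw_score_days Consecutive daily observations at score 4
#'   needed to fire (default 3: two observations span at most 48 h).
#' @param weight_loss_fraction Fractional weight loss limit.
#' @return A list of class `endpoint_rule`.
#' @export
endpoint_rule <- function(joint_limit_in = 0.4, max_paw_score_days = 3L,
                          weight_loss_fraction = 0.20) {
  if (joint_limit_in <= 0 || weight_loss_fraction <= 0) {
    stop_config("endpoint limits must be positive")
  }
  structure(list(joint_limit_in = joint_limit_in,
                 max_paw_score_days = as.integer(max_paw_score_days),
                 weight_loss_fraction = weight_loss_fraction),
            class = "endpoint_rule")
}

check_series <- function(days, values) {
  if (length(days) != length(values)) stop_domain("days and values differ in length")
  obs <- !is.na(values)
  if (!any(obs)) stop_domain("series has no observed days")
  o <- order(days)
  list(days = as.integer(days[o]), values = values[o])
}

#' Detect disease onset in a per-day metric series
#'
#' Onset is the earliest day consistently above threshold, operationalised
#' as: value strictly greater than the threshold on day `d` and on day
#' `d + 1` (or `d` is the last observed day).  A single-day excursion is a
#' blip, not onset.
#'
#' @param days Integer study days.
#' @param values Metric values (NA = unobserved).
#' @param threshold Threshold (strict `>`).
#' @return The onset day, or `NA_integer_` if never consistently above.
#' @examples
#' detect_onset(10:14, c(1, 2, 6, 7, 8), 5)   # 12
#' detect_onset(10:14, c(1, 6, 2, 6, 7), 5)   # 13: day 11 is a blip
#' @export
detect_onset <- function(days, values, threshold) {
  s <- check_series(days, values)
  obs_days <- s$days[!is.na(s$values)]
  obs_vals <- s$values[!is.na(s$values)]
  last_day <- obs_days[length(obs_days)]
  for (i in seq_along(obs_days)) {
    if (obs_vals[i] <= threshold) next
    d <- obs_days[i]
    if (d == last_day) return(d)
    j <- match(d + 1L, obs_days)
    if (!is.na(j) && obs_vals[j] > threshold) return(d)
  }
  NA_integer_
}

#' Call disease incidence for one animal
#'
#' `TRUE` iff any observed value is strictly greater than the threshold at
#' any point in the series.
#'
#' @inheritParams detect_onset
#' @return Logical.
#' @export
call_incidence <- function(days, values, threshold) {
  s <- check_series(days, values)
  any(s$values > threshold, na.rm = TRUE)
}

#' Disease severity at study end or humane endpoint
#'
#' For DAI and arthritis score, severity is the value on the last study day
#' (or the censoring day).  For joint size it is the change between that
#' day and induction day 0.  If the end day itself is unobserved the last
#' prior observation is used (with a message).
#'
#' @inheritParams detect_onset
#' @param kind `"dai"`, `"score"` or `"joint"`.
#' @param censor_day Optional humane-endpoint day truncating the series.
#' @return Severity in the metric's units.
#' @export
severity_at_end <- function(days, values, kind = c("dai", "score", "joint"),
                            censor_day = NULL) {
  kind <- match.arg(kind)
  s <- check_series(days, values)
  end_day <- max(s$days[!is.na(s$values)])
  if (!is.null(censor_day) && !is.na(censor_day)) {
    end_day <- min(end_day, censor_day)
  }
  usable <- s$days <= end_day & !is.na(s$values)
  if (!any(usable)) stop_domain("no observation at or before the end day")
  take <- max(s$days[usable])
  if (take != end_day) {
    message(sprintf("end day %d unobserved; using last prior observation (day %d)",
                    end_day, take))
  }
  v_end <- s$values[s$days == take]
  if (kind != "joint") return(v_end)
  if (!(0L %in% s$days) || is.na(s$values[s$days == 0L])) {
    stop_domain("joint-size severity requires an observed day-0 value")
  }
  v_end - s$values[s$days == 0L]
}

#' Cumulative metric burden over threshold
#'
#' Sum over observed days of the excess of the metric above the threshold
#' (`max(0, value - threshold)`), a cumulative arthritis index.
#'
#' @inheritParams detect_onset
#' @return Non-negative area in metric-units x days.
#' @examples
#' cumulative_over_threshold(1:3, c(6, 7, 4), 5)  # 3
#' @export
cumulative_over_threshold <- function(days, values, threshold) {
  s <- check_series(days, values)
  sum(pmax(0, s$values - threshold), na.rm = TRUE)
}

# longest-run helper: day on which `hits` has been TRUE for `k` consecutive
# observations, or NA
run_fire_day <- function(days, hits, k) {
  r <- rle(hits)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= k)
  if (length(ok) == 0) return(NA_integer_)
  starts <- ends - r$lengths + 1L
  days[starts[ok[1]] + k - 1L]
}

#' Apply humane-endpoint censoring criteria
#'
#' Scans one animal's clinical record and returns the earliest day on which
#' any criterion of the [endpoint_rule()] fires.  Baseline body weight is
#' the day-0 observation (or the earliest available).  The sustained-score
#' criterion fires on the day the required run of consecutive maximal
#' scores completes.
#'
#' @param clinical Long tibble `(animal_id, study_day, metric, value)` for
#'   one animal with metrics `joint_left_in`, `joint_right_in`,
#'   `paw_score_left`, `paw_score_right`, `body_weight_g`.
#' @param rule An [endpoint_rule()].
#' @return Censor day (integer) or `NA_integer_`.
#' @export
apply_humane_endpoint <- function(clinical, rule = endpoint_rule()) {
  if (length(unique(clinical$animal_id)) > 1) {
    stop_domain("apply_humane_endpoint expects a single animal's record")
  }
  wide <- tidyr::pivot_wider(clinical, id_cols = "study_day",
                             names_from = "metric", values_from = "value")
  wide <- wide[order(wide$study_day), ]
  fires <- NA_integer_

  jmax <- pmax(wide$joint_left_in %||% NA_real_,
               wide$joint_right_in %||% NA_real_, na.rm = TRUE)
  hit <- which(!is.na(jmax) & jmax >= rule$joint_limit_in)
  if (length(hit)) fires <- min(fires, wide$study_day[hit[1]], na.rm = TRUE)

  for (paw in c("paw_score_left", "paw_score_right")) {
    if (is.null(wide[[paw]])) next
    obs <- !is.na(wide[[paw]])
    d <- run_fire_day(wide$study_day[obs], wide[[paw]][obs] == 4,
                      rule$max_paw_score_days)
    if (!is.na(d)) fires <- min(fires, d, na.rm = TRUE)
  }

  if (!is.null(wide$body_weight_g)) {
    obs <- which(!is.na(wide$body_weight_g))
    if (length(obs)) {
      base_i <- if (any(wide$study_day[obs] == 0)) obs[wide$study_day[obs] == 0][1] else obs[1]
      bw0 <- wide$body_weight_g[base_i]
      hit <- obs[wide$body_weight_g[obs] < (1 - rule$weight_loss_fraction) * bw0]
      if (length(hit)) fires <- min(fires, wide$study_day[hit[1]], na.rm = TRUE)
    }
  }
  as.integer(fires)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-animal, per-day metric series derived from the long clinical record:
# joint_size = max of left/right ankle; arthritis_score = sum of hind paws
clinical_series <- function(clinical) {
  wide <- tidyr::pivot_wider(clinical, id_cols = c("animal_id", "study_day"),
                             names_from = "metric", values_from = "value")
  tibble::tibble(
    animal_id = wide$animal_id,
    study_day = wide$study_day,
    joint_size = max_joint_size(wide$joint_left_in %||% NA_real_,
                                wide$joint_right_in %||% NA_real_),
    arthritis_score = total_arthritis_score(wide$paw_score_left %||% NA_real_,
                                            wide$paw_score_right %||% NA_real_))
}

#' Per-animal disease outcomes for every metric
#'
#' Applies humane-endpoint censoring, then calls incidence, onset and
#' severity per animal for the DAI, the joint-size series (maximum of the
#' two ankles) and the total arthritis score, restricted to study days 0 to
#' `final_day` (and to days at or before the censor day).
#'
#' @param dai Tibble from [dai_series()].
#' @param clinical Long clinical tibble (all animals).
#' @param thresholds A [threshold_config()].
#' @param rule An [endpoint_rule()].
#' @param calendar A [study_calendar()].
#' @return Tibble `(animal_id, metric, arthritic, onset_day, severity,
#'   censor_day)`, metrics `dai`, `joint_size`, `arthritis_score`.
#' @export
animal_outcomes <- function(dai, clinical, thresholds = threshold_config(),
                            rule = endpoint_rule(),
                            calendar = study_calendar()) {
  cs <- clinical_series(clinical)
  ids <- union(unique(dai$animal_id), unique(cs$animal_id))
  specs <- list(
    dai = list(thr = thresholds$dai, kind = "dai"),
    joint_size = list(thr = thresholds$joint_size_in, kind = "joint"),
    arthritis_score = list(thr = thresholds$arthritis_score, kind = "score"))

  rows <- lapply(ids, function(id) {
    censor <- apply_humane_endpoint(clinical[clinical$animal_id == id, ], rule)
    end_day <- if (is.na(censor)) calendar$final_day else min(censor, calendar$final_day)
    get_series <- function(metric) {
      if (metric == "dai") {
        x <- dai[dai$animal_id == id, ]
        list(days = x$study_day, values = x$dai)
      } else {
        x <- cs[cs$animal_id == id, ]
        list(days = x$study_day, values = x[[metric]])
      }
    }
    dplyr::bind_rows(lapply(names(specs), function(metric) {
      sr <- get_series(metric)
      keep <- sr$days >= 0 & sr$days <= end_day
      days <- sr$days[keep]; values <- sr$values[keep]
      if (length(days) == 0 || all(is.na(values))) {
        return(tibble::tibble(animal_id = id, metric = metric,
                              arthritic = NA, onset_day = NA_integer_,
                              severity = NA_real_, censor_day = censor))
      }
      onset <- detect_onset(days, values, specs[[metric]]$thr)
      tibble::tibble(
        animal_id = id, metric = metric,
        arthritic = call_incidence(days, values, specs[[metric]]$thr),
        onset_day = onset,
        severity = severity_at_end(days, values, specs[[metric]]$kind,
                                   censor_day = censor),
        censor_day = censor)
    }))
  })
  dplyr::bind_rows(rows)
}
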