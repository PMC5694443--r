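#' Disease incidence as an integer percentage
#'
#' @param n_arthritic,n_total Counts with `0 <= n_arthritic <= n_total`,
#'   `n_total > 0`.
#' @return `round(100 * n_arthritic / n_total)` to the nearest integer
#'   percent.
#' @examples
#' incidence_percent(29, 32)  # 91
#' incidence_percent(7, 9)    # 78
#' @export
incidence_percent <- function(n_arthritic, n_total) {
  if (any(n_total <= 0)) stop_domain("n_total must be > 0")
  if (any(n_arthritic < 0 | n_arthritic > n_total)) {
    stop_domain("n_arthritic must be in [0, n_total]")
  }
  round_half_up(100 * n_arthritic / n_total)
}

check_xy <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_domain("need at least 3 complete pairs")
  list(x = x, y = y)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) if either
#'   input has zero variance.
#' @export
pearson_r <- function(x, y) {
  p <- check_xy(x, y)
  if (sd(p$x) == 0 || sd(p$y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(p$x, p$y)
}

#' Simple linear regression of an outcome on a disease metric
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept,
#' Pearson correlation and its square (the R-squared of a simple
#' regression).
#'
#' @param x Predictor (e.g. per-animal DAI severity).
#' @param y Outcome (e.g. total histopathology score).
#' @return A list `(slope, intercept, pearson_r, r_squared)`.
#' @examples
#' fit_regression(1:5, 2 * (1:5) + 1)
#' @export
fit_regression <- function(x, y) {
  p <- check_xy(x, y)
  if (sd(p$x) == 0) {
    warning("zero variance in x: regression undefined", call. = FALSE)
    return(list(slope = NA_real_, intercept = NA_real_,
                pearson_r = NA_real_, r_squared = NA_real_))
  }
  fit <- lm(y ~ x, data = p)
  r <- if (sd(p$y) == 0) NA_real_ else cor(p$x, p$y)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       pearson_r = r,
       r_squared = if (is.na(r)) 0 else r^2)
}

#' Rank compounds by mean therapeutic response
#'
#' Competition ranking of per-compound severity means within each
#' assessment method: the smallest mean (largest disease attenuation) gets
#' rank 1, ties share the minimal rank and the following rank is skipped
#' (1, 2, 2, 4).  Compounds with a missing mean are excluded from that
#' method's ranking (rank `NA`, logged).
#'
#' @param means Tibble with columns `compound`, `method`, `mean`.
#' @return The input with a `rank` column added.
#' @examples
#' rank_compounds(tibble::tibble(compound = c("A", "B", "C"),
#'                               method = "dai", mean = c(7.9, 7.4, 7.9)))
#' @export
rank_compounds <- function(means) {
  req <- c("compound", "method", "mean")
  if (!all(req %in% names(means))) {
    stop_validation("means must have columns %s", paste(req, collapse = ", "))
  }
  if (length(unique(means$compound)) < 2) {
    stop_domain("need at least 2 compounds to rank")
  }
  if (anyNA(means$mean)) {
    message(sprintf("%d compound-method mean(s) missing; excluded from ranking",
                    sum(is.na(means$mean))))
  }
  means |>
    dplyr::group_by(.data$method) |>
    dplyr::mutate(rank = dplyr::if_else(
      is.na(.data$mean), NA_integer_,
      as.integer(rank(.data$mean, ties.method = "min", na.last = "keep")))) |>
    dplyr::ungroup()
}

#' Order dose groups by disease attenuation
#'
#' Renders the dose-effect ordering (e.g. `"High > Low > Medium"`) from the
#' reduction in mean severity each dose achieved relative to vehicle.
#' Larger reduction comes first; exactly tied doses are joined with `"="`.
#'
#' @param reductions Named numeric vector of severity reductions for the
#'   `low`, `medium` and `high` doses (all three required).
#' @return A single ordering string.
#' @examples
#' dose_effect_ordering(c(low = 2.0, medium = 0.5, high = 3.0))
#' @export
dose_effect_ordering <- function(reductions) {
  want <- c("low", "medium", "high")
  names(reductions) <- tolower(names(reductions))
  if (!setequal(names(reductions), want) || anyNA(reductions)) {
    stop_domain("reductions must be a complete named vector over low/medium/high")
  }
  o <- order(-reductions)
  lab <- paste0(toupper(substring(names(reductions)[o], 1, 1)),
                substring(names(reductions)[o], 2))
  sep <- ifelse(diff(reductions[o]) == 0, " = ", " > ")
  paste0(lab[1], paste0(sep, lab[-1], collapse = ""))
}

#' Group summary of incidence, onset and severity
#'
#' One row per group and metric: incidence as an integer percent, onset
#' mean and SD over arthritic animals only (`NA` when none), and severity
#' mean and SD over all animals (non-arthritic animals contribute their
#' end-of-study values).
#'
#' @param outcomes Tibble from [animal_outcomes()] with a `group` column
#'   (join the study's animal table first).
#' @return Tibble `(group, metric, n, n_arthritic, incidence_pct,
#'   onset_mean, onset_sd, severity_mean, severity_sd)`.
#' @export
summarize_group <- function(outcomes) {
  if (!"group" %in% names(outcomes)) {
    stop_validation("outcomes must carry a 'group' column")
  }
  if (nrow(outcomes) == 0) stop_domain("no outcomes to summarise")
  outcomes |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_arthritic = sum(.data$arthritic, na.rm = TRUE),
      incidence_pct = incidence_percent(n_arthritic, n),
      onset_mean = if (sum(!is.na(.data$onset_day)) > 0)
        mean(.data$onset_day[!is.na(.data$onset_day)]) else NA_real_,
      onset_sd = if (sum(!is.na(.data$onset_day)) > 1)
        sd(.data$onset_day[!is.na(.data$onset_day)]) else NA_real_,
      severity_mean = mean(.data$severity, na.rm = TRUE),
      severity_sd = sd(.data$severity, na.rm = TRUE),
      .groups = "drop")
}

#' Per-animal severity table across metrics
#'
#' Wide per-animal severities (DAI, joint-size change, arthritis score)
#' joined with mean histopathology scores, the shape used for
#' cross-correlation and regression against histopathology.
#'
#' @param outcomes Tibble from [animal_outcomes()].
#' @param histopath Side-level histopathology tibble (optional).
#' @return Tibble keyed by `animal_id` with columns `dai`, `joint_size`,
#'   `arthritis_score` and, when available, the five subscore means and
#'   `histo_total`.
#' @export
severity_table <- function(outcomes, histopath = NULL) {
  wide <- tidyr::pivot_wider(outcomes, id_cols = "animal_id",
                             names_from = "metric", values_from = "severity")
  if (!is.null(histopath) && nrow(histopath) > 0) {
    wide <- dplyr::left_join(wide, histopath_summary(histopath), by = "animal_id")
  }
  wide
}

#' Cross-correlation matrix between severity measures
#'
#' Pairwise Pearson correlations between the severity columns, with `NA`
#' where a column has zero variance (e.g. control-only runs).
#'
#' @param severities Tibble from [severity_table()].
#' @return Tibble: one row per variable, one column per variable, plus a
#'   leading `variable` column.
#' @export
correlation_table <- function(severities) {
  vars <- setdiff(names(severities), "animal_id")
  m <- as.matrix(severities[, vars])
  cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- NA_real_
  out <- tibble::as_tibble(cc)
  dplyr::bind_cols(tibble::tibble(variable = vars), out)
}
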