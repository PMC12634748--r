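# Crude incidence rates with exact Poisson (Garwood) confidence intervals,
# progression-time summaries, and baseline characterization tables.

garwood_ci <- function(n_events, person_years, level) {
  a <- 1 - level
  low <- ifelse(n_events == 0, 0,
                qchisq(a / 2, 2 * n_events) / (2 * person_years))
  high <- qchisq(1 - a / 2, 2 * (n_events + 1)) / (2 * person_years)
  list(low = low, high = high)
}

#' Crude incidence rate with exact Poisson confidence interval
#'
#' The point estimate is `ir_scale * n_events / person_years`. The interval is
#' the exact (Garwood) Poisson interval from chi-square quantiles:
#' `lower = qchisq(alpha/2, 2k) / (2T)` (zero when `k = 0`) and
#' `upper = qchisq(1 - alpha/2, 2(k + 1)) / (2T)`, scaled to `ir_scale`
#' person-years. The upper bound is strictly positive even with zero events,
#' which is the behaviour wanted for rare outcomes.
#'
#' @param n_events non-negative event count.
#' @param person_years positive person-time at risk, years.
#' @param config a [study_config()] (supplies `ir_scale` and `ci_level`).
#' @return a one-row tibble `n_events, person_years, ir, ci_low, ci_high`.
#' @export
crude_ir <- function(n_events, person_years, config = study_config()) {
  if (any(person_years <= 0)) {
    abort("person_years must be positive; a zero-exposure rate is undefined",
          class = "iimcohort_undefined_rate_error")
  }
  ci <- garwood_ci(n_events, person_years, config$ci_level)
  tibble::tibble(
    n_events = as.integer(n_events),
    person_years = person_years,
    ir = config$ir_scale * n_events / person_years,
    ci_low = config$ir_scale * ci$low,
    ci_high = config$ir_scale * ci$high
  )
}

#' Aggregate observations into per-group, per-outcome incidence rates
#'
#' For every `group` (cohort or matched-control group) and outcome:
#' the number of washout-eligible subjects, the number with an event, the
#' summed person-years at risk, and the crude rate with its exact interval.
#' Groups with zero eligible person-time are emitted with `rate_defined =
#' FALSE` and missing rate columns rather than dropped.
#'
#' @param observations output of [compute_observations()].
#' @param config a [study_config()].
#' @return a tibble of incidence results.
#' @export
aggregate_ir <- function(observations, config = study_config()) {
  res <- observations |>
    dplyr::group_by(.data$group, .data$outcome) |>
    dplyr::summarise(
      n_eligible = sum(.data$eligible),
      n_events = sum(.data$eligible & !is.na(.data$event_date)),
      person_years = sum(.data$time_at_risk_days) / DAYS_PER_YEAR,
      .groups = "drop"
    ) |>
    dplyr::mutate(rate_defined = .data$person_years > 0)
  ok <- res$rate_defined
  res$ir <- res$ci_low <- res$ci_high <- NA_real_
  if (any(ok)) {
    ci <- garwood_ci(res$n_events[ok], res$person_years[ok], config$ci_level)
    res$ir[ok] <- config$ir_scale * res$n_events[ok] / res$person_years[ok]
    res$ci_low[ok] <- config$ir_scale * ci$low
    res$ci_high[ok] <- config$ir_scale * ci$high
  }
  res
}

#' Progression-time summaries
#'
#' Per group and outcome: the arithmetic mean time from index to the event
#' (years, among subjects with the event; absent when there is none) and the
#' crude cumulative percentage of washout-eligible subjects with the event by
#' 6 months, 1 year, and 2 years after index (calendar-month horizons;
#' subjects censored earlier remain in the denominator).
#'
#' @param observations output of [compute_observations()].
#' @param config a [study_config()].
#' @return a tibble with columns `group, outcome, n_eligible, n_events,
#'   mean_time_to_event_years, pct_at_6mo, pct_at_1y, pct_at_2y`.
#' @export
progression_summary <- function(observations, config = study_config()) {
  observations |>
    dplyr::filter(.data$eligible) |>
    dplyr::mutate(
      h6 = add_months(.data$index_date, 6L),
      h12 = add_months(.data$index_date, 12L),
      h24 = add_months(.data$index_date, 24L),
      has_event = !is.na(.data$event_date)
    ) |>
    dplyr::group_by(.data$group, .data$outcome) |>
    dplyr::summarise(
      n_eligible = dplyr::n(),
      n_events = sum(.data$has_event),
      mean_time_to_event_years = ifelse(
        sum(.data$has_event) == 0, NA_real_,
        mean(as.numeric(.data$event_date[.data$has_event] -
                          .data$index_date[.data$has_event])) / DAYS_PER_YEAR),
      pct_at_6mo = 100 * sum(.data$has_event & .data$event_date <= .data$h6) /
        dplyr::n(),
      pct_at_1y = 100 * sum(.data$has_event & .data$event_date <= .data$h12) /
        dplyr::n(),
      pct_at_2y = 100 * sum(.data$has_event & .data$event_date <= .data$h24) /
        dplyr::n(),
      .groups = "drop"
    )
}

#' Baseline characterization tables
#'
#' For each subject group: mean and sample (n-1) standard deviation of age at
#' index; for every non-IIM diagnosis category, the count and percentage of
#' subjects with at least one matching event in the half-open 12-month
#' baseline window `[index - baseline_months, index)`; and for every
#' medication class, the count and percentage with a record in the 7-month
#' medication window `[index - eaw_months, index + 1 month)` (the exposure
#' assessment window plus the first post-index month).
#'
#' @param subjects tibble with `subject_id`, `group`, `index_date`.
#' @param events validated, sorted event table.
#' @param patients validated patient table.
#' @param config a [study_config()].
#' @return a long tibble `group, section, variable, n_group, count, percent,
#'   mean, sd` (mean/sd populated only for the demographic rows).
#' @export
baseline_tables <- function(subjects, events, patients, config = study_config()) {
  s <- subjects[, c("subject_id", "group", "index_date")]
  s$base_start <- add_months(s$index_date, -config$baseline_months)
  s$med_start <- add_months(s$index_date, -config$eaw_months)
  s$med_end <- add_months(s$index_date, config$med_window_months - config$eaw_months)
  pt <- patients[match(s$subject_id, patients$patient_id), , drop = FALSE]
  s$age <- age_in_years(pt$birth_date, s$index_date)
  sizes <- dplyr::count(s, .data$group, name = "n_group")

  demo <- s |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_group = dplyr::n(), mean = mean(.data$age),
                     sd = sd(.data$age), .groups = "drop") |>
    dplyr::mutate(section = "demographics", variable = "age_at_index",
                  count = NA_integer_, percent = NA_real_)

  ev <- dplyr::inner_join(events, s, by = c(patient_id = "subject_id"))
  comorb <- ev |>
    dplyr::filter(.data$event_class == "diagnosis",
                  !(.data$category %in% IIM_SUBTYPES),
                  .data$date >= .data$base_start, .data$date < .data$index_date) |>
    dplyr::distinct(.data$patient_id, .data$group, .data$category) |>
    dplyr::count(.data$group, .data$category, name = "count") |>
    dplyr::mutate(section = "comorbidity")
  meds <- ev |>
    dplyr::filter(.data$event_class == "medication",
                  .data$date >= .data$med_start, .data$date < .data$med_end) |>
    dplyr::distinct(.data$patient_id, .data$group, .data$category) |>
    dplyr::count(.data$group, .data$category, name = "count") |>
    dplyr::mutate(section = "medication")

  flags <- dplyr::bind_rows(comorb, meds) |>
    dplyr::rename(variable = "category") |>
    dplyr::left_join(sizes, by = "group") |>
    dplyr::mutate(percent = 100 * .data$count / .data$n_group,
                  mean = NA_real_, sd = NA_real_)

  dplyr::bind_rows(demo, flags) |>
    dplyr::select("group", "section", "variable", "n_group", "count",
                  "percent", "mean", "sd") |>
    dplyr::arrange(.data$group, .data$section, .data$variable)
}
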