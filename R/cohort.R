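# Incident-case identification. The phenotyping algorithm opens a 6-month
# exposure assessment window (EAW) at the first in-period DM/PM diagnosis,
# tallies weighted diagnosis counts inside the half-open window
# [first_dx, first_dx + eaw_months), assigns the subtype with the highest
# count (ties go to the last diagnosis in the window), applies the
# outpatient-only confirmation rule, and sets the index date to the first day
# after the window. Scalar operations below are deliberately plain base R so
# they can also serve as a fast reference path; build_cohorts() is the
# vectorized driver used on whole populations.

IIM_SUBTYPES <- c("DM", "PM")

EXCLUSION_REASONS <- c("no_iim_dx", "not_in_idn", "insufficient_pre_activity",
                       "insufficient_post_activity", "prior_iim_dx",
                       "outpatient_rule_failed", "under_min_age", "no_subtype")

is_iim_dx <- function(events) {
  events$event_class == "diagnosis" & events$category %in% IIM_SUBTYPES
}

#' First in-period IIM diagnosis for one patient
#'
#' @param events one patient's events, sorted by date.
#' @param config a [study_config()].
#' @return the earliest DM/PM diagnosis date inside the study period
#'   (inclusive of both bounds), or `NA` if there is none.
#' @export
first_iim_diagnosis <- function(events, config) {
  d <- events$date[is_iim_dx(events) &
                     events$date >= config$study_start &
                     events$date <= config$study_end]
  if (length(d) == 0) as.Date(NA) else min(d)
}

#' Eligibility screen for one candidate case
#'
#' Checks, in this fixed order, that the patient receives care through an
#' integrated delivery network, has database activity from at least
#' `pre_activity_months` before through `post_activity_months` after the first
#' in-period diagnosis, and has no DM/PM diagnosis anywhere in the database
#' before that date. The first failing check is the recorded exclusion reason.
#'
#' @param patient a one-row patient record.
#' @param events the patient's events, sorted by date.
#' @param first_dx the first in-period IIM diagnosis date.
#' @param config a [study_config()].
#' @return `"pass"`, or the exclusion reason as a string.
#' @export
check_eligibility <- function(patient, events, first_dx, config) {
  stopifnot(!is.na(first_dx))
  if (!isTRUE(patient$in_idn)) return("not_in_idn")
  if (patient$activity_start > add_months(first_dx, -config$pre_activity_months)) {
    return("insufficient_pre_activity")
  }
  if (patient$activity_end < add_months(first_dx, config$post_activity_months)) {
    return("insufficient_post_activity")
  }
  iim_dates <- events$date[is_iim_dx(events)]
  if (any(iim_dates < first_dx)) return("prior_iim_dx")
  "pass"
}

#' Weighted diagnosis tally over the exposure assessment window
#'
#' Counts DM and PM diagnoses dated in the half-open window
#' `[eaw_start, eaw_end)`, weighting inpatient diagnoses `inpatient_weight`
#' (default 2) and outpatient diagnoses `outpatient_weight` (default 1), and
#' records what the last in-window diagnosis was. When several diagnoses share
#' the final date, the later input row wins; input row order within a date is
#' therefore part of the contract (see [read_events()]).
#'
#' @param events one patient's events, sorted by `(date, input row)`.
#' @param eaw_start,eaw_end window bounds; `eaw_end` is exclusive.
#' @param config a [study_config()].
#' @return a list with `dm_count`, `pm_count`, `dm_outpatient_n`,
#'   `pm_outpatient_n`, `has_any_inpatient`, `last_dx_subtype`, `last_dx_date`,
#'   and `degenerate` (TRUE when no DM/PM diagnosis falls in the window).
#' @export
score_eaw <- function(events, eaw_start, eaw_end, config) {
  stopifnot(eaw_start < eaw_end)
  keep <- is_iim_dx(events) & events$date >= eaw_start & events$date < eaw_end
  cat <- events$category[keep]
  setting <- events$setting[keep]
  if (length(cat) == 0) {
    return(list(dm_count = 0L, pm_count = 0L, dm_outpatient_n = 0L,
                pm_outpatient_n = 0L, has_any_inpatient = FALSE,
                last_dx_subtype = NA_character_, last_dx_date = as.Date(NA),
                degenerate = TRUE))
  }
  w <- ifelse(setting == "inpatient", config$inpatient_weight,
              config$outpatient_weight)
  last <- length(cat) # rows sorted by date, stable: last row is the tiebreak winner
  list(
    dm_count = as.integer(sum(w[cat == "DM"])),
    pm_count = as.integer(sum(w[cat == "PM"])),
    dm_outpatient_n = sum(cat == "DM" & setting == "outpatient"),
    pm_outpatient_n = sum(cat == "PM" & setting == "outpatient"),
    has_any_inpatient = any(setting == "inpatient"),
    last_dx_subtype = cat[last],
    last_dx_date = events$date[keep][last],
    degenerate = FALSE
  )
}

#' Subtype assignment from an EAW score
#'
#' The provisional subtype is the one with the larger weighted count, with
#' equal counts resolved to the subtype of the last in-window diagnosis. A
#' patient whose window contains no inpatient diagnosis must additionally have
#' at least `min_outpatient_only` outpatient diagnoses of the winning subtype;
#' otherwise no subtype is assigned.
#'
#' @param score a [score_eaw()] result.
#' @param config a [study_config()].
#' @return `"DM"`, `"PM"`, or `NA_character_` when no assignment is possible.
#' @export
assign_subtype <- function(score, config) {
  if (isTRUE(score$degenerate)) return(NA_character_)
  subtype <- if (score$dm_count > score$pm_count) "DM"
  else if (score$pm_count > score$dm_count) "PM"
  else score$last_dx_subtype
  if (!score$has_any_inpatient) {
    own_out <- if (subtype == "DM") score$dm_outpatient_n else score$pm_outpatient_n
    if (own_out < config$min_outpatient_only) return(NA_character_)
  }
  subtype
}

#' Build the incident DM/PM/JDM/JPM cohorts
#'
#' Vectorized composition of [first_iim_diagnosis()], [check_eligibility()],
#' [score_eaw()], and [assign_subtype()] over a whole population. Patients with
#' no in-period DM/PM diagnosis are silently outside the study; every patient
#' with at least one appears exactly once, either in the assignments or in the
#' exclusions with a single primary reason (the first failing check in the
#' fixed order not_in_idn, insufficient_pre_activity,
#' insufficient_post_activity, prior_iim_dx, outpatient_rule_failed,
#' under_min_age). The index date is the day after the half-open EAW, i.e.
#' `first_dx + eaw_months`; juveniles are those aged at least `min_age_years`
#' but under `adult_age_years` (completed years) at index.
#'
#' @param patients validated patient table.
#' @param events validated, sorted event table.
#' @param config a [study_config()].
#' @return a list of two tibbles, `assignments` and `exclusions`.
#' @export
build_cohorts <- function(patients, events, config = study_config()) {
  iim <- dplyr::filter(events, .data$event_class == "diagnosis",
                       .data$category %in% IIM_SUBTYPES)
  in_period <- dplyr::filter(iim, .data$date >= config$study_start,
                             .data$date <= config$study_end)
  if (nrow(in_period) == 0) {
    return(list(assignments = empty_assignments(), exclusions = empty_exclusions()))
  }
  firsts <- in_period |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_iim_date = min(.data$date), .groups = "drop")
  ever <- iim |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_ever = min(.data$date), .groups = "drop")

  d <- firsts |>
    dplyr::inner_join(patients, by = "patient_id") |>
    dplyr::left_join(ever, by = "patient_id") |>
    dplyr::mutate(
      pre_bound = add_months(.data$first_iim_date, -config$pre_activity_months),
      post_bound = add_months(.data$first_iim_date, config$post_activity_months),
      reason = dplyr::case_when(
        !.data$in_idn ~ "not_in_idn",
        .data$activity_start > .data$pre_bound ~ "insufficient_pre_activity",
        .data$activity_end < .data$post_bound ~ "insufficient_post_activity",
        .data$first_ever < .data$first_iim_date ~ "prior_iim_dx",
        TRUE ~ NA_character_
      )
    )
  excl_pre <- dplyr::filter(d, !is.na(.data$reason))
  elig <- d |>
    dplyr::filter(is.na(.data$reason)) |>
    dplyr::mutate(
      eaw_start = .data$first_iim_date,
      eaw_end = add_months(.data$first_iim_date, config$eaw_months),
      index_date = .data$eaw_end
    )

  scores <- iim |>
    dplyr::inner_join(dplyr::select(elig, "patient_id", "eaw_start", "eaw_end"),
                      by = "patient_id") |>
    dplyr::filter(.data$date >= .data$eaw_start, .data$date < .data$eaw_end) |>
    dplyr::mutate(w = dplyr::if_else(.data$setting == "inpatient",
                                     config$inpatient_weight,
                                     config$outpatient_weight)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      dm_count = as.integer(sum(.data$w[.data$category == "DM"])),
      pm_count = as.integer(sum(.data$w[.data$category == "PM"])),
      dm_out = sum(.data$category == "DM" & .data$setting == "outpatient"),
      pm_out = sum(.data$category == "PM" & .data$setting == "outpatient"),
      any_inpt = any(.data$setting == "inpatient"),
      last_subtype = .data$category[dplyr::n()],
      .groups = "drop"
    )

  a <- elig |>
    dplyr::left_join(scores, by = "patient_id") |>
    dplyr::mutate(
      subtype = dplyr::case_when(
        .data$dm_count > .data$pm_count ~ "DM",
        .data$pm_count > .data$dm_count ~ "PM",
        TRUE ~ .data$last_subtype
      ),
      own_out = dplyr::if_else(.data$subtype == "DM", .data$dm_out, .data$pm_out),
      age_at_index = age_in_years(.data$birth_date, .data$index_date),
      reason = dplyr::case_when(
        .data$dm_count + .data$pm_count == 0L ~ "no_subtype",
        !.data$any_inpt & .data$own_out < config$min_outpatient_only ~
          "outpatient_rule_failed",
        .data$age_at_index < config$min_age_years ~ "under_min_age",
        TRUE ~ NA_character_
      )
    )

  assignments <- a |>
    dplyr::filter(is.na(.data$reason)) |>
    dplyr::mutate(cohort = paste0(
      dplyr::if_else(.data$age_at_index < config$adult_age_years, "J", ""),
      .data$subtype)) |>
    dplyr::select("patient_id", "first_iim_date", "eaw_start", "eaw_end",
                  "index_date", "subtype", "cohort", "age_at_index",
                  "dm_count", "pm_count")
  exclusions <- dplyr::bind_rows(
    dplyr::select(excl_pre, "patient_id", "reason"),
    a |> dplyr::filter(!is.na(.data$reason)) |>
      dplyr::select("patient_id", "reason")
  ) |>
    dplyr::mutate(reason = factor(.data$reason, levels = EXCLUSION_REASONS))
  list(assignments = assignments, exclusions = exclusions)
}

empty_assignments <- function() {
  tibble::tibble(patient_id = character(), first_iim_date = as.Date(character()),
                 eaw_start = as.Date(character()), eaw_end = as.Date(character()),
                 index_date = as.Date(character()), subtype = character(),
                 cohort = character(), age_at_index = integer(),
                 dm_count = integer(), pm_count = integer())
}

empty_exclusions <- function() {
  tibble::tibble(patient_id = character(),
                 reason = factor(character(), levels = EXCLUSION_REASONS))
}
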