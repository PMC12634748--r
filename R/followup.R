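# Follow-up and per-outcome observation engine. Follow-up runs from the index
# date to the earliest of death, end of database activity, a disqualifying
# post-index DM/PM diagnosis (for cases: one inpatient or two outpatient
# diagnoses of the non-cohort subtype; for controls: any DM/PM diagnosis), or
# the end of the study period. Each of the 13 outcomes is then observed
# independently: a prior occurrence in the 12-month washout removes the
# subject from that outcome's follow-up only, and follow-up for an outcome
# ends at its first post-index occurrence.

#' The 13 study outcomes
#'
#' Interstitial lung disease (with and without oxygen requirement), heart
#' failure, cardiomyopathy, cardiac dysrhythmia, ischemic heart disease,
#' dysphagia, esophageal dysmotility, GERD, peptic ulcer, malignancy excluding
#' non-melanoma skin cancer, the six main malignancies (ovarian, lung,
#' pancreatic, stomach, colorectal, basal/squamous cell), and all-cause death.
#' The two malignancy labels are independent: an event mapped to both counts
#' for both, and washout eligibility is assessed per label.
#'
#' @return character vector of the closed outcome label set.
#' @export
outcome_labels <- function() {
  c("ILD", "ILD_requiring_oxygen", "heart_failure", "cardiomyopathy",
    "cardiac_dysrhythmia", "ischemic_heart_disease", "dysphagia",
    "esophageal_dysmotility", "GERD", "peptic_ulcer", "malignancy_excl_NMSC",
    "malignancy_main6", "all_cause_death")
}

CENSOR_REASONS <- c("death", "end_of_activity", "subtype_switch",
                    "control_iim_dx", "study_end")

#' Follow-up end and censoring reason for one subject
#'
#' Candidate end dates are the death date, the end of database activity, the
#' disqualifying-diagnosis date (cases: first post-index inpatient diagnosis
#' of the other subtype, or the second post-index outpatient one, whichever is
#' earlier; controls: first post-index DM/PM diagnosis of any kind), and the
#' study end. The follow-up end is the earliest candidate, with same-day ties
#' resolved by the fixed priority death > end_of_activity > subtype_switch /
#' control_iim_dx > study_end. "Post-index" includes the index date itself.
#'
#' @param patient one-row patient record.
#' @param events the subject's events, sorted.
#' @param index_date follow-up start.
#' @param role `"case"` or `"control"`.
#' @param cohort_subtype the case's cohort-defining subtype (`NULL` for
#'   controls).
#' @param config a [study_config()].
#' @return list with `fu_end` (Date) and `censor_reason` (string).
#' @export
compute_followup_end <- function(patient, events, index_date, role,
                                 cohort_subtype = NULL, config = study_config()) {
  stopifnot(role %in% c("case", "control"))
  death <- patient$death_date
  if (!is.na(death) && death < index_date) {
    abort("death precedes the index date; such a subject cannot be followed",
          class = "iimcohort_contract_error")
  }
  iim <- events[is_iim_dx(events) & events$date >= index_date, , drop = FALSE]
  if (role == "case") {
    other <- setdiff(IIM_SUBTYPES, cohort_subtype)
    oth <- iim[iim$category == other, , drop = FALSE]
    inpt <- oth$date[oth$setting == "inpatient"]
    outp <- oth$date[oth$setting == "outpatient"]
    trigger <- suppressWarnings(min(
      if (length(inpt) >= 1) inpt[1] else as.Date(Inf),
      if (length(outp) >= 2) outp[2] else as.Date(Inf)
    ))
    trigger_reason <- "subtype_switch"
  } else {
    trigger <- if (nrow(iim) >= 1) iim$date[1] else as.Date(Inf)
    trigger_reason <- "control_iim_dx"
  }
  cand <- c(
    death = if (is.na(death)) as.Date(Inf) else death,
    end_of_activity = patient$activity_end,
    trigger = trigger,
    study_end = config$study_end
  )
  fu_end <- min(cand)
  reason <- c("death", "end_of_activity", trigger_reason,
              "study_end")[which(cand == fu_end)[1]]
  list(fu_end = fu_end, censor_reason = reason)
}

#' Washout eligibility for one subject and outcome
#'
#' A subject is ineligible for an outcome when an event of that category is
#' dated inside the half-open washout window
#' `[index - washout_months, index)`. All-cause death has no washout and is
#' always eligible.
#'
#' @param outcome one of [outcome_labels()].
#' @param events the subject's events.
#' @param index_date the index date.
#' @param config a [study_config()].
#' @return logical; `TRUE` when the subject is followed for the outcome.
#' @export
washout_eligibility <- function(outcome, events, index_date, config = study_config()) {
  if (outcome == "all_cause_death") return(TRUE)
  w0 <- add_months(index_date, -config$washout_months)
  !any(events$category == outcome & events$date >= w0 & events$date < index_date)
}

#' Per-outcome observations for one subject
#'
#' @param patient one-row patient record (supplies the death date).
#' @param events the subject's events, sorted.
#' @param index_date,fu_end the follow-up interval.
#' @param config a [study_config()].
#' @return a tibble with one row per outcome: `outcome`, `eligible`,
#'   `event_date` (NA when none), `time_at_risk_days`.
#' @export
observe_events <- function(patient, events, index_date, fu_end,
                           config = study_config()) {
  rows <- lapply(outcome_labels(), function(o) {
    eligible <- washout_eligibility(o, events, index_date, config)
    if (!eligible) {
      return(tibble::tibble(outcome = o, eligible = FALSE,
                            event_date = as.Date(NA), time_at_risk_days = 0))
    }
    if (o == "all_cause_death") {
      ed <- patient$death_date
      ed <- if (!is.na(ed) && ed <= fu_end) ed else as.Date(NA)
    } else {
      hits <- events$date[events$category == o &
                            events$date >= index_date & events$date <= fu_end]
      ed <- if (length(hits) > 0) min(hits) else as.Date(NA)
    }
    tibble::tibble(outcome = o, eligible = TRUE, event_date = ed,
                   time_at_risk_days = as.numeric((if (is.na(ed)) fu_end else ed) -
                                                    index_date))
  })
  dplyr::bind_rows(rows)
}

#' Follow-up intervals for a subject table
#'
#' Vectorized driver over a subject table (`subject_id`, `role`, `group`,
#' `index_date`, and `subtype` for cases). Controls' censoring uses a single
#' DM/PM diagnosis of any kind; cases use the 1-inpatient / 2-outpatient
#' other-subtype rule.
#'
#' @param subjects tibble as above; `subject_id` values are patient ids.
#' @param events validated, sorted event table for the whole population.
#' @param patients validated patient table.
#' @param config a [study_config()].
#' @return `subjects` extended with `fu_end` and `censor_reason`.
#' @export
compute_follow_up <- function(subjects, events, patients, config = study_config()) {
  pt <- patients[match(subjects$subject_id, patients$patient_id), , drop = FALSE]
  if (any(!is.na(pt$death_date) & pt$death_date < subjects$index_date)) {
    abort("death precedes the index date for some subject",
          class = "iimcohort_contract_error")
  }
  iim <- dplyr::filter(events, .data$event_class == "diagnosis",
                       .data$category %in% IIM_SUBTYPES)

  case_tbl <- subjects[subjects$role == "case",
                       c("subject_id", "index_date", "subtype")]
  sw <- iim |>
    dplyr::inner_join(case_tbl, by = c(patient_id = "subject_id")) |>
    dplyr::filter(.data$date >= .data$index_date,
                  .data$category != .data$subtype) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      inpt1 = dplyr::first(.data$date[.data$setting == "inpatient"],
                           default = as.Date(NA)),
      outp2 = dplyr::nth(.data$date[.data$setting == "outpatient"], 2,
                         default = as.Date(NA)),
      .groups = "drop"
    ) |>
    dplyr::mutate(trigger = pmin(.data$inpt1, .data$outp2, na.rm = TRUE))

  ctrl_tbl <- subjects[subjects$role == "control", c("subject_id", "index_date")]
  cd0 <- iim |>
    dplyr::inner_join(ctrl_tbl, by = c(patient_id = "subject_id")) |>
    dplyr::filter(.data$date >= .data$index_date)
  cd <- if (nrow(cd0) > 0) {
    cd0 |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(trigger = min(.data$date), .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(), trigger = as.Date(character()))
  }

  trig <- dplyr::bind_rows(sw[, c("patient_id", "trigger")], cd)
  out <- subjects
  out$death_date <- pt$death_date
  out$activity_end <- pt$activity_end
  out$trigger <- trig$trigger[match(out$subject_id, trig$patient_id)]

  far <- as.Date(Inf)
  d_death <- dplyr::coalesce(out$death_date, far)
  d_trig <- dplyr::coalesce(out$trigger, far)
  fu_end <- pmin(d_death, out$activity_end, d_trig, config$study_end)
  out$fu_end <- fu_end
  out$censor_reason <- dplyr::case_when(
    d_death == fu_end ~ "death",
    out$activity_end == fu_end ~ "end_of_activity",
    d_trig == fu_end ~ dplyr::if_else(out$role == "case",
                                      "subtype_switch", "control_iim_dx"),
    TRUE ~ "study_end"
  )
  out$death_date <- NULL
  out$activity_end <- NULL
  out$trigger <- NULL
  out
}

#' Per-outcome observations for a subject table
#'
#' Vectorized driver over the output of [compute_follow_up()]: for every
#' subject and every outcome, washout eligibility, the first post-index event
#' date within follow-up (death from the patient table for all-cause death),
#' and the time at risk in days. Ineligible subject-outcome pairs contribute
#' zero risk time.
#'
#' @param followup subject table with `fu_end` from [compute_follow_up()].
#' @param events validated, sorted event table.
#' @param patients validated patient table.
#' @param config a [study_config()].
#' @return a tibble with one row per subject x outcome.
#' @export
compute_observations <- function(followup, events, patients,
                                 config = study_config()) {
  fu <- followup[, c("subject_id", "role", "group", "index_date", "fu_end")]
  fu$wash_start <- add_months(fu$index_date, -config$washout_months)
  pt <- patients[match(fu$subject_id, patients$patient_id), , drop = FALSE]
  fu$death_date <- pt$death_date

  oev <- dplyr::filter(events, .data$category %in% outcome_labels(),
                       .data$category != "all_cause_death") |>
    dplyr::inner_join(fu[, c("subject_id", "index_date", "fu_end", "wash_start")],
                      by = c(patient_id = "subject_id"))
  washed <- oev |>
    dplyr::filter(.data$date >= .data$wash_start, .data$date < .data$index_date) |>
    dplyr::distinct(.data$patient_id, .data$category) |>
    dplyr::mutate(ineligible = TRUE)
  firsts0 <- oev |>
    dplyr::filter(.data$date >= .data$index_date, .data$date <= .data$fu_end)
  firsts <- if (nrow(firsts0) > 0) {
    firsts0 |>
      dplyr::group_by(.data$patient_id, .data$category) |>
      dplyr::summarise(event_date = min(.data$date), .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(), category = character(),
                   event_date = as.Date(character()))
  }

  grid <- tidyr::crossing(fu, outcome = outcome_labels()) |>
    dplyr::left_join(washed, by = c(subject_id = "patient_id",
                                    outcome = "category")) |>
    dplyr::left_join(firsts, by = c(subject_id = "patient_id",
                                    outcome = "category")) |>
    dplyr::mutate(
      eligible = .data$outcome == "all_cause_death" |
        !dplyr::coalesce(.data$ineligible, FALSE),
      event_date = dplyr::if_else(
        .data$outcome == "all_cause_death",
        dplyr::if_else(!is.na(.data$death_date) & .data$death_date <= .data$fu_end,
                       .data$death_date, as.Date(NA)),
        .data$event_date),
      event_date = dplyr::if_else(.data$eligible, .data$event_date, as.Date(NA)),
      time_at_risk_days = dplyr::if_else(
        .data$eligible,
        as.numeric(dplyr::coalesce(.data$event_date, .data$fu_end) - .data$index_date),
        0)
    ) |>
    dplyr::select("subject_id", "role", "group", "index_date", "outcome",
                  "eligible", "event_date", "time_at_risk_days")
  grid
}
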