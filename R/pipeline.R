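#' Run the full natural-history pipeline
#'
#' Convenience driver composing the whole analysis: cohort construction,
#' control-pool building and 1:1 matching, follow-up and per-outcome
#' observation, and incidence-rate / progression-time estimation. Cases carry
#' their cohort (`DM`, `PM`, `JDM`, `JPM`) as analysis group; each matched
#' control is analysed in the `MC_<cohort>` group of its case, with follow-up
#' starting on the case's index date.
#'
#' @param patients validated patient table.
#' @param events validated, sorted event table.
#' @param config a [study_config()].
#' @param match_seed seed for the matching step (defaults to the config seed).
#' @return a list: `assignments`, `exclusions`, `pairs`, `unmatched`,
#'   `followup`, `observations`, `incidence`, `progression`, `baseline`.
#' @export
run_study <- function(patients, events, config = study_config(),
                      match_seed = config$rng_seed) {
  ch <- build_cohorts(patients, events, config)
  pool <- build_control_pool(patients, events)
  mt <- match_controls(ch$assignments, pool, patients, config, seed = match_seed)

  cases <- tibble::tibble(
    subject_id = ch$assignments$patient_id,
    role = "case",
    group = ch$assignments$cohort,
    index_date = ch$assignments$index_date,
    subtype = ch$assignments$subtype
  )
  case_group <- setNames(cases$group, cases$subject_id)
  controls <- tibble::tibble(
    subject_id = mt$pairs$control_id,
    role = "control",
    group = paste0("MC_", case_group[mt$pairs$case_id]),
    index_date = mt$pairs$index_date,
    subtype = NA_character_
  )
  subjects <- dplyr::bind_rows(cases, controls)

  fu <- compute_follow_up(subjects, events, patients, config)
  obs <- compute_observations(fu, events, patients, config)
  list(
    assignments = ch$assignments,
    exclusions = ch$exclusions,
    pairs = mt$pairs,
    unmatched = mt$unmatched,
    followup = fu,
    observations = obs,
    incidence = aggregate_ir(obs, config),
    progression = progression_summary(obs, config),
    baseline = baseline_tables(subjects, events, patients, config)
  )
}

#' Round an incidence table for report display
#'
#' Rates and bounds to one decimal, mirroring the usual per-100-person-year
#' table layout; the machine-precision columns stay available in the input.
#'
#' @param incidence output of [aggregate_ir()].
#' @return a tibble with display columns `ir_fmt` like `"10.3 (9.6-11.1)"`.
#' @export
format_ir_table <- function(incidence) {
  incidence |>
    dplyr::mutate(ir_fmt = dplyr::if_else(
      .data$rate_defined,
      sprintf("%.1f (%.1f-%.1f)", .data$ir, .data$ci_low, .data$ci_high),
      "undefined (0 PY)")) |>
    dplyr::select("group", "outcome", "n_eligible", "n_events",
                  "person_years", "ir_fmt")
}
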