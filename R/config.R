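#' Study configuration
#'
#' Bundles every tunable study parameter. Defaults reproduce the design used
#' for the incident dermatomyositis (DM) / polymyositis (PM) natural-history
#' analysis: a study period of 2016-01-01 to 2021-03-31, a 6-month exposure
#' assessment window (EAW) opened by the first in-period DM/PM diagnosis,
#' 6 months of required database activity on either side of that diagnosis, a
#' 12-month pre-index washout per outcome, a 12-month baseline window, a
#' 7-month medication window (EAW plus the first post-index month), inpatient
#' diagnoses weighted 2 and outpatient 1 in the EAW tally, a minimum of 2
#' same-subtype outpatient diagnoses for patients with no inpatient diagnosis,
#' enrolment from age 12 with the adult cohorts starting at 18, and incidence
#' rates per 100 person-years with exact 95% intervals.
#'
#' All windows derived from these parameters are half-open `[start, end)`:
#' an event dated exactly on a window's end date falls outside it.
#'
#' @param study_start,study_end study period bounds (`Date` or "YYYY-MM-DD").
#' @param eaw_months length of the exposure assessment window, months.
#' @param pre_activity_months,post_activity_months continuous-activity margins
#'   required before/after the first in-period diagnosis, months.
#' @param washout_months per-outcome washout before the index date, months.
#' @param baseline_months baseline characterization window, months.
#' @param med_window_months medication assessment window, months (EAW + 1).
#' @param min_age_years minimum age at index for enrolment.
#' @param adult_age_years age at index separating juvenile from adult cohorts.
#' @param inpatient_weight,outpatient_weight EAW diagnosis weights.
#' @param min_outpatient_only minimum same-subtype outpatient diagnoses for
#'   patients whose EAW contains no inpatient diagnosis.
#' @param ir_scale person-years multiplier for reported rates (100 = per 100 PY).
#' @param ci_level two-sided confidence level for rate intervals.
#' @param rng_seed integer seed used by seeded pipeline steps (matching).
#' @return an object of class `study_config` (a validated named list).
#' @export
study_config <- function(study_start = "2016-01-01",
                         study_end = "2021-03-31",
                         eaw_months = 6L,
                         pre_activity_months = 6L,
                         post_activity_months = 6L,
                         washout_months = 12L,
                         baseline_months = 12L,
                         med_window_months = eaw_months + 1L,
                         min_age_years = 12L,
                         adult_age_years = 18L,
                         inpatient_weight = 2L,
                         outpatient_weight = 1L,
                         min_outpatient_only = 2L,
                         ir_scale = 100,
                         ci_level = 0.95,
                         rng_seed = 20160101L) {
  cfg <- list(
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    eaw_months = as.integer(eaw_months),
    pre_activity_months = as.integer(pre_activity_months),
    post_activity_months = as.integer(post_activity_months),
    washout_months = as.integer(washout_months),
    baseline_months = as.integer(baseline_months),
    med_window_months = as.integer(med_window_months),
    min_age_years = as.integer(min_age_years),
    adult_age_years = as.integer(adult_age_years),
    inpatient_weight = as.integer(inpatient_weight),
    outpatient_weight = as.integer(outpatient_weight),
    min_outpatient_only = as.integer(min_outpatient_only),
    ir_scale = as.numeric(ir_scale),
    ci_level = as.numeric(ci_level),
    rng_seed = as.integer(rng_seed)
  )
  if (is.na(cfg$study_start) || is.na(cfg$study_end)) {
    abort("study_start and study_end must be valid dates",
          class = "iimcohort_config_error")
  }
  if (cfg$study_start >= cfg$study_end) {
    abort("study_start must precede study_end", class = "iimcohort_config_error")
  }
  month_pars <- c("eaw_months", "pre_activity_months", "post_activity_months",
                  "washout_months", "baseline_months", "med_window_months",
                  "inpatient_weight", "outpatient_weight", "min_outpatient_only")
  bad <- month_pars[vapply(month_pars, function(p) cfg[[p]] < 1L, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("parameters must be >= 1: ", paste(bad, collapse = ", ")),
          class = "iimcohort_config_error")
  }
  if (!(cfg$ci_level > 0 && cfg$ci_level < 1)) {
    abort("ci_level must lie strictly between 0 and 1",
          class = "iimcohort_config_error")
  }
  structure(cfg, class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML keys mirror the arguments of [study_config()]; omitted keys take
#' the documented defaults, unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return a `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "iimcohort_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "iimcohort_config_error")
  }
  do.call(study_config, vals)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  study period : %s .. %s\n", x$study_start, x$study_end))
  cat(sprintf("  EAW          : %d months (weights %d inpatient / %d outpatient, >=%d outpatient-only)\n",
              x$eaw_months, x$inpatient_weight, x$outpatient_weight,
              x$min_outpatient_only))
  cat(sprintf("  activity     : %d months pre / %d months post first diagnosis\n",
              x$pre_activity_months, x$post_activity_months))
  cat(sprintf("  washout      : %d months; baseline %d; medications %d\n",
              x$washout_months, x$baseline_months, x$med_window_months))
  cat(sprintf("  ages         : enrol >= %d, adult >= %d\n",
              x$min_age_years, x$adult_age_years))
  cat(sprintf("  rates        : per %g PY, %g%% exact Poisson CI\n",
              x$ir_scale, 100 * x$ci_level))
  invisible(x)
}
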