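# 1:1 matched-control construction: controls are drawn without replacement
# from the disease-free pool, matched exactly on birth year and natal sex,
# with follow-up starting on the case's index date.

#' Disease-free control pool
#'
#' @param patients validated patient table.
#' @param events validated event table.
#' @return character vector of patient ids with no DM/PM diagnosis at any date.
#' @export
build_control_pool <- function(patients, events) {
  ever <- unique(events$patient_id[is_iim_dx(events)])
  setdiff(patients$patient_id, ever)
}

#' Match one control per case without replacement
#'
#' Cases are processed in a seeded random order, so that scarce controls are
#' not systematically awarded to low-id cases. For each case the candidates
#' are the not-yet-used pool members with the same birth year and sex whose
#' activity interval contains the case's index date; one is drawn uniformly at
#' random and the matched control inherits the case's exact index date (which
#' trivially satisfies the same-month/year follow-up start). A case with no
#' remaining candidate is reported unmatched; it stays in cohort-level rate
#' analyses and only its matched-control comparison is lost.
#'
#' @param assignments cohort assignments from [build_cohorts()].
#' @param pool control-pool ids from [build_control_pool()].
#' @param patients validated patient table.
#' @param config a [study_config()]; supplies the default seed.
#' @param seed RNG seed for the processing order and candidate draws.
#' @return a list with `pairs` (tibble `case_id, control_id, birth_year, sex,
#'   index_date`) and `unmatched` (character vector of case ids).
#' @export
match_controls <- function(assignments, pool, patients, config = study_config(),
                           seed = config$rng_seed) {
  set.seed(seed)
  pt <- patients[match(pool, patients$patient_id), , drop = FALSE]
  strata_key <- paste(lubridate::year(pt$birth_date), pt$sex)
  stratum_members <- split(seq_len(nrow(pt)), strata_key)

  cs <- assignments
  cs_pt <- patients[match(cs$patient_id, patients$patient_id), , drop = FALSE]
  cs_key <- paste(lubridate::year(cs_pt$birth_date), cs_pt$sex)
  order_ <- sample.int(nrow(cs))

  used <- logical(nrow(pt))
  ctrl <- rep(NA_character_, nrow(cs))
  for (i in order_) {
    members <- stratum_members[[cs_key[i]]]
    if (is.null(members)) next
    idx <- cs$index_date[i]
    cand <- members[!used[members] &
                      pt$activity_start[members] <= idx &
                      pt$activity_end[members] >= idx]
    if (length(cand) == 0) next
    pick <- cand[sample.int(length(cand), 1L)]
    used[pick] <- TRUE
    ctrl[i] <- pt$patient_id[pick]
  }

  matched <- !is.na(ctrl)
  pairs <- tibble::tibble(
    case_id = cs$patient_id[matched],
    control_id = ctrl[matched],
    birth_year = as.integer(lubridate::year(cs_pt$birth_date[matched])),
    sex = cs_pt$sex[matched],
    index_date = cs$index_date[matched]
  )
  list(pairs = pairs, unmatched = cs$patient_id[!matched])
}
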