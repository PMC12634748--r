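# Shared fixtures and independent oracles. Oracles are written in a
# deliberately different style from the package internals (explicit per-event
# scans, numeric root-finding) so they can adjudicate, not echo.

mk_patient <- function(patient_id = "p1",
                       birth_date = "1970-01-01",
                       sex = "female",
                       activity_start = "2014-01-01",
                       activity_end = "2022-12-31",
                       death_date = NA,
                       in_idn = TRUE) {
  tibble::tibble(
    patient_id = patient_id,
    birth_date = as.Date(birth_date),
    sex = sex,
    activity_start = as.Date(activity_start),
    activity_end = as.Date(activity_end),
    death_date = as.Date(death_date),
    in_idn = in_idn
  )
}

mk_events <- function(patient_id, date, category,
                      setting = "outpatient", event_class = "diagnosis") {
  ev <- tibble::tibble(
    patient_id = patient_id, date = as.Date(date), category = category,
    setting = setting, event_class = event_class
  )
  dplyr::arrange(ev, patient_id, date)
}

# --- brute-force subtype oracle -------------------------------------------
# Scans a diagnosis sequence event by event, accumulating counts; the "last
# diagnosis" is simply the final element of the (date-then-row ordered)
# sequence. Input: vectors of subtype, setting, day offsets (non-decreasing).
oracle_assign <- function(subtype, setting, config) {
  dm <- 0; pm <- 0; dm_out <- 0; pm_out <- 0; any_in <- FALSE
  for (i in seq_along(subtype)) {
    w <- if (setting[i] == "inpatient") config$inpatient_weight else config$outpatient_weight
    if (subtype[i] == "DM") dm <- dm + w else pm <- pm + w
    if (setting[i] == "outpatient") {
      if (subtype[i] == "DM") dm_out <- dm_out + 1 else pm_out <- pm_out + 1
    } else {
      any_in <- TRUE
    }
  }
  winner <- if (dm > pm) "DM" else if (pm > dm) "PM" else subtype[length(subtype)]
  if (!any_in) {
    own <- if (winner == "DM") dm_out else pm_out
    if (own < config$min_outpatient_only) return(NA_character_)
  }
  winner
}

# --- day-by-day follow-up oracle ------------------------------------------
# Walks every day from index to study end, firing the first trigger in the
# fixed priority order death > end_of_activity > switch/control dx > study end.
oracle_followup <- function(patient, events, index_date, role, subtype, config) {
  iim <- events[events$event_class == "diagnosis" &
                  events$category %in% c("DM", "PM"), , drop = FALSE]
  other <- setdiff(c("DM", "PM"), subtype)
  for (d in seq(index_date, config$study_end, by = "day")) {
    d <- as.Date(d, origin = "1970-01-01")
    if (!is.na(patient$death_date) && patient$death_date == d) {
      return(list(fu_end = d, censor_reason = "death"))
    }
    if (patient$activity_end == d) {
      return(list(fu_end = d, censor_reason = "end_of_activity"))
    }
    if (role == "case") {
      post <- iim[iim$date >= index_date & iim$date <= d &
                    iim$category == other, , drop = FALSE]
      hit <- any(post$date == d & post$setting == "inpatient") ||
        (sum(post$setting == "outpatient") >= 2 &&
           sort(post$date[post$setting == "outpatient"])[2] == d)
      if (hit) return(list(fu_end = d, censor_reason = "subtype_switch"))
    } else {
      if (any(iim$date == d & iim$date >= index_date)) {
        return(list(fu_end = d, censor_reason = "control_iim_dx"))
      }
    }
  }
  list(fu_end = config$study_end, censor_reason = "study_end")
}

# --- numeric-inversion Poisson CI oracle ----------------------------------
# Exact interval by inverting the Poisson tail probabilities with uniroot.
oracle_poisson_ci <- function(k, person_years, level = 0.95) {
  a <- (1 - level) / 2
  upper <- stats::uniroot(function(lam) stats::ppois(k, lam * person_years) - a,
                          c(1e-12, (k + 50) / person_years * 10),
                          tol = 1e-12)$root
  lower <- if (k == 0) 0 else {
    stats::uniroot(function(lam) {
      stats::ppois(k - 1, lam * person_years, lower.tail = FALSE) - a
    }, c(1e-14, (k + 50) / person_years * 10), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

# All EAW diagnosis sequences of length <= max_len over subtype x setting,
# with every non-decreasing day pattern (i.e. every tie configuration).
# Returns a list of tibbles (day offsets from the window start; the first
# event always opens the window at day 0).
enumerate_eaw_sequences <- function(max_len = 4) {
  seqs <- list()
  for (len in seq_len(max_len)) {
    combos <- expand.grid(rep(list(1:4), len)) # 1..4 = DM/in DM/out PM/in PM/out
    day_patterns <- day_patterns_nondecreasing(len)
    for (ci in seq_len(nrow(combos))) {
      code <- as.integer(combos[ci, ])
      subtype <- c("DM", "DM", "PM", "PM")[code]
      setting <- c("inpatient", "outpatient", "inpatient", "outpatient")[code]
      for (dp in day_patterns) {
        seqs[[length(seqs) + 1L]] <-
          list(subtype = subtype, setting = setting, day = dp - dp[1])
      }
    }
  }
  seqs
}

day_patterns_nondecreasing <- function(len) {
  if (len == 1) return(list(1L))
  grid <- expand.grid(rep(list(seq_len(len)), len))
  keep <- apply(grid, 1, function(r) all(diff(as.integer(r)) >= 0))
  lapply(which(keep), function(i) as.integer(grid[i, ]))
}

sort_events_for_test <- function(ev) dplyr::arrange(ev, patient_id, date)
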