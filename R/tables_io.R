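# Tabular input/output. All files are plain CSV with a header row and
# ISO-8601 (YYYY-MM-DD) dates; the reading functions validate schema and
# record-level invariants before anything downstream runs.

PATIENT_COLS <- c("patient_id", "birth_date", "sex", "activity_start",
                  "activity_end", "death_date", "in_idn")
EVENT_COLS <- c("patient_id", "date", "category", "setting", "event_class")
SEX_LEVELS <- c("female", "male")
SETTING_LEVELS <- c("inpatient", "outpatient")
EVENT_CLASSES <- c("diagnosis", "medication", "procedure")

read_delim_checked <- function(path, required) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "iimcohort_io_error")
  }
  d <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       na = character(), progress = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "iimcohort_schema_error")
  }
  d
}

parse_date_col <- function(x, col, required = TRUE) {
  blank <- !nzchar(x) | is.na(x)
  out <- as.Date(rep(NA_integer_, length(x)))
  parsed <- as.Date(x[!blank], format = "%Y-%m-%d", optional = TRUE)
  bad <- which(!blank)[is.na(parsed)]
  if (required) bad <- union(bad, which(blank))
  if (length(bad) > 0) {
    abort(sprintf("column '%s': unparseable date at data row(s) %s", col,
                  paste(head(sort(bad), 5), collapse = ", ")),
          class = "iimcohort_parse_error")
  }
  out[!blank] <- parsed
  out
}

#' Read the patient table
#'
#' Expects columns `patient_id, birth_date, sex, activity_start, activity_end,
#' death_date, in_idn` (death_date empty when absent, `in_idn` coded 0/1).
#' Each patient carries one continuous database-activity interval; the
#' integrated-delivery-network requirement is the boolean `in_idn` flag.
#'
#' @param path path to a CSV file.
#' @return a tibble with one validated row per patient, input order preserved.
#' @export
read_patients <- function(path) {
  d <- read_delim_checked(path, PATIENT_COLS)
  out <- tibble::tibble(
    patient_id = d$patient_id,
    birth_date = parse_date_col(d$birth_date, "birth_date"),
    sex = d$sex,
    activity_start = parse_date_col(d$activity_start, "activity_start"),
    activity_end = parse_date_col(d$activity_end, "activity_end"),
    death_date = parse_date_col(d$death_date, "death_date", required = FALSE),
    in_idn = d$in_idn %in% c("1", "TRUE", "true")
  )
  if (!all(d$in_idn %in% c("0", "1", "TRUE", "FALSE", "true", "false"))) {
    abort("in_idn must be coded 0/1", class = "iimcohort_schema_error")
  }
  validate_patients(out)
}

#' Validate a patient tibble against its invariants
#'
#' @param patients a tibble shaped like [read_patients()] output.
#' @return the input, invisibly validated.
#' @export
validate_patients <- function(patients) {
  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate patient_id: ", paste(unique(dup), collapse = ", ")),
          class = "iimcohort_integrity_error")
  }
  if (!all(patients$sex %in% SEX_LEVELS)) {
    abort("sex must be 'female' or 'male'", class = "iimcohort_integrity_error")
  }
  if (any(patients$activity_end < patients$activity_start)) {
    abort("activity_end precedes activity_start", class = "iimcohort_integrity_error")
  }
  has_death <- !is.na(patients$death_date)
  if (any(patients$death_date[has_death] < patients$activity_start[has_death])) {
    abort("death_date precedes activity_start", class = "iimcohort_integrity_error")
  }
  patients
}

#' Read the clinical event table
#'
#' Expects columns `patient_id, date, category, setting, event_class`.
#' `category` is a pre-mapped label: a disease subtype (`DM`, `PM`), an
#' outcome label (see [outcome_labels()]), a comorbidity/clinical
#' characteristic, or a medication class. Diagnosis rows must carry an
#' `inpatient` or `outpatient` setting; medication/procedure rows leave it
#' blank. Rows may arrive in any order; the result is sorted by
#' `(patient_id, date)` with ties kept in input-row order, which is the order
#' every downstream tie-break refers to.
#'
#' @param path path to a CSV file.
#' @return a tibble of validated, sorted clinical events.
#' @export
read_events <- function(path) {
  d <- read_delim_checked(path, EVENT_COLS)
  out <- tibble::tibble(
    patient_id = d$patient_id,
    date = parse_date_col(d$date, "date"),
    category = d$category,
    setting = dplyr::if_else(nzchar(d$setting) & !(d$setting %in% c("n/a", "NA")),
                             d$setting, NA_character_),
    event_class = d$event_class
  )
  validate_events(out)
  sort_events(out)
}

#' @rdname read_events
#' @param events a tibble shaped like [read_events()] output.
#' @export
validate_events <- function(events) {
  if (any(!nzchar(events$category) | is.na(events$category))) {
    abort("category must be non-empty", class = "iimcohort_schema_error")
  }
  if (!all(events$event_class %in% EVENT_CLASSES)) {
    abort("event_class must be diagnosis, medication, or procedure",
          class = "iimcohort_schema_error")
  }
  dx <- events$event_class == "diagnosis"
  if (!all(events$setting[dx] %in% SETTING_LEVELS)) {
    abort("diagnosis rows must have setting 'inpatient' or 'outpatient'",
          class = "iimcohort_schema_error")
  }
  ok <- is.na(events$setting) | events$setting %in% SETTING_LEVELS
  if (!all(ok)) {
    abort("unknown setting value", class = "iimcohort_schema_error")
  }
  events
}

sort_events <- function(events) {
  # dplyr::arrange is stable, so same-(patient, date) rows keep input order
  dplyr::arrange(events, .data$patient_id, .data$date)
}

#' Map coded events to analysis category labels
#'
#' The pipeline consumes pre-mapped category labels; this helper applies a
#' user-supplied code-to-category map (e.g. ICD-10-CM or NDC codes curated
#' elsewhere) to a raw event table that carries a `code` column instead of
#' `category`. Many codes may map to one category. Unmapped events are either
#' dropped with an informative count, or rejected.
#'
#' @param raw_events tibble with columns `patient_id, date, code, setting,
#'   event_class`.
#' @param code_map two-column tibble/data.frame `code, category`, or a named
#'   character vector `c(code = category)`.
#' @param unmapped `"drop"` (default; drops are counted and reported) or
#'   `"error"`.
#' @return a sorted, validated event tibble as from [read_events()].
#' @export
apply_code_map <- function(raw_events, code_map, unmapped = c("drop", "error")) {
  unmapped <- match.arg(unmapped)
  if (is.character(code_map)) {
    code_map <- tibble::tibble(code = names(code_map) %||% character(0),
                               category = unname(code_map))
  }
  stopifnot(all(c("code", "category") %in% names(code_map)),
            all(c("patient_id", "date", "code") %in% names(raw_events)))
  if (anyDuplicated(code_map$code)) {
    abort("code_map assigns a code to more than one category",
          class = "iimcohort_integrity_error")
  }
  hit <- match(raw_events$code, code_map$code)
  n_drop <- sum(is.na(hit))
  if (n_drop > 0 && unmapped == "error") {
    abort(sprintf("%d event(s) carry unmapped codes", n_drop),
          class = "iimcohort_schema_error")
  }
  if (n_drop > 0) {
    inform(sprintf("apply_code_map: dropped %d unmapped event(s)", n_drop))
  }
  kept <- raw_events[!is.na(hit), , drop = FALSE]
  out <- tibble::tibble(
    patient_id = kept$patient_id,
    date = as.Date(kept$date),
    category = code_map$category[hit[!is.na(hit)]],
    setting = if ("setting" %in% names(kept)) kept$setting else NA_character_,
    event_class = if ("event_class" %in% names(kept)) kept$event_class else "diagnosis"
  )
  validate_events(out)
  sort_events(out)
}

#' Write patient and event tables
#'
#' Inverse of the readers: ISO dates, empty string for an absent death date or
#' setting, `in_idn` coded 0/1. A written table read back reproduces the input
#' exactly.
#'
#' @param patients,events tibbles as produced by the readers or the simulator.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  d <- patients
  d$in_idn <- as.integer(d$in_idn)
  readr::write_csv(d, path, na = "")
  invisible(path)
}

#' @rdname write_patients
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path, na = "")
  invisible(path)
}
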