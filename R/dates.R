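#' Calendar-month arithmetic with end-of-month clamping
#'
#' Adds `k` calendar months to a date, keeping the day of month and clamping to
#' the last day of the target month when it is shorter (e.g. Aug 31 + 6 months
#' is Feb 28, or Feb 29 in a leap year). All month-denominated study windows
#' (exposure assessment window, activity margins, washout, baseline, medication
#' window) use this arithmetic, so seams are consistent everywhere.
#'
#' @param x a `Date` vector.
#' @param k integer number of months; may be negative.
#' @return a `Date` vector of the same length as `x`.
#' @examples
#' add_months(as.Date("2016-08-31"), 6) # "2017-02-28"
#' @export
add_months <- function(x, k) {
  stopifnot(inherits(x, "Date"), length(k) == 1L, !is.na(k))
  x %m+% lubridate::period(months = as.integer(k))
}

#' Completed age in years at a reference date
#'
#' Age by the usual epidemiologic convention: number of whole birthdays
#' attained on or before `ref` (the anniversary day itself counts as attained).
#'
#' @param birth,ref `Date` vectors (recycled to common length).
#' @return integer vector of completed years.
#' @export
age_in_years <- function(birth, ref) {
  stopifnot(inherits(birth, "Date"), inherits(ref, "Date"))
  y <- lubridate::year(ref) - lubridate::year(birth)
  not_yet <- (lubridate::month(ref) < lubridate::month(birth)) |
    (lubridate::month(ref) == lubridate::month(birth) &
       lubridate::mday(ref) < lubridate::mday(birth))
  as.integer(y - not_yet)
}

# days -> person-years
DAYS_PER_YEAR <- 365.25

#' @importFrom lubridate %m+% %m-%
NULL
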