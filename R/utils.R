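# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding as used for all published rates and ages: ties go away
#' from zero (`round_half_up(12.45, 1)` is 12.5), unlike base [round()] which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(12.4749 * 10) / 10
#' round_half_up(c(2.5, -2.5), 0)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small guard against representation error just below a tie point
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

ymd <- function(y, m, d) as.Date(sprintf("%04d-%02d-%02d", y, m, d))

date_year <- function(d) as.integer(format(d, "%Y"))
date_month <- function(d) as.integer(format(d, "%m"))

#' Completed age in years at January 1 of a year
#'
#' All cohort classifications are anchored at January 1, so ages are reported
#' as completed years at that date.
#'
#' @param birth_date `Date` vector of birth dates.
#' @param year integer anchor year.
#' @return integer vector of completed ages.
#' @export
age_at_jan1 <- function(birth_date, year) {
  stopifnot(inherits(birth_date, "Date"))
  by <- date_year(birth_date)
  # birthday reached at Jan 1 only for Jan 1 births
  bday_reached <- date_month(birth_date) == 1L & as.integer(format(birth_date, "%d")) == 1L
  as.integer(year - by - 1L + bday_reached)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg, ...) {
  stop(sprintf("invalid `%s`: %s", field, sprintf(msg, ...)), call. = FALSE)
}
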