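# 365-day working calendar. Every year is treated as having 365 days:
# 29 Feb shares day-of-year 59 with 28 Feb, so 1 Mar is day 60 and windows
# (spring GDD5, recording seasons) align across years.

.cumdays <- c(0L, cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L)))

#' Day of year on the 365-day calendar
#'
#' Converts calendar dates to a 1-based day-of-year in which every year has
#' 365 days; 29 February maps to day 59 (the 28 February convention), so
#' 1 March is always day 60.
#'
#' @param date a `Date` vector (or something coercible by [as.Date()]).
#' @return integer day-of-year in `1:365`.
#' @export
doy365 <- function(date) {
  lt <- as.POSIXlt(as.Date(date))
  m <- lt$mon + 1L
  d <- lt$mday
  d[m == 2L & d == 29L] <- 28L
  .cumdays[m] + d
}

#' Date from a 365-day day-of-year
#'
#' Inverse of [doy365()] on the non-leap calendar: day 60 is always 1 March.
#' 29 February is never produced.
#'
#' @param year integer year(s).
#' @param doy integer day(s) of year in `1:365`.
#' @return a `Date` vector.
#' @export
date_from_doy365 <- function(year, doy) {
  doy <- as.integer(doy)
  if (any(doy < 1L | doy > 365L)) stop("doy must be in 1..365")
  m <- findInterval(doy - 1L, .cumdays)
  d <- doy - .cumdays[m]
  as.Date(sprintf("%04d-%02d-%02d", as.integer(year), m, d))
}

# Recording windows, as day-of-year ranges. Transects run 1 Apr-29 Sep;
# traps run all year.
#' Recording window for a scheme
#'
#' @param scheme `"transect"` (weekly walks, 1 April-29 September, days
#'   91-272) or `"trap"` (light traps, all year, days 1-365).
#' @return integer vector `c(first_day, last_day)`.
#' @export
scheme_window <- function(scheme = c("transect", "trap")) {
  scheme <- match.arg(scheme)
  if (scheme == "transect") c(91L, 272L) else c(1L, 365L)
}

# Spring degree-day accumulation window: 1 Mar-31 May inclusive (92 days).
.gdd5_window <- c(60L, 151L)
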