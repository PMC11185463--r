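#' Ordinal dates within a nesting season
#'
#' A nesting season runs from October 1 of `season_start_year` to
#' September 30 of the following calendar year. Day 1 is October 1; the last
#' day is 365, or 366 when the season contains a February 29.
#'
#' @param date a `Date` (or string coercible to one, ISO-8601).
#' @param season_start_year integer calendar year of the October that opens
#'   the season.
#' @return `to_ordinal()` returns an integer day-of-season;
#'   `from_ordinal()` returns a `Date`.
#' @examples
#' to_ordinal("2017-10-01", 2017)  # 1
#' to_ordinal("2017-12-30", 2017)  # 91
#' from_ordinal(91, 2017)          # "2017-12-30"
#' @export
to_ordinal <- function(date, season_start_year) {
  date <- as.Date(date)
  season_start_year <- as.integer(season_start_year)
  start <- season_start(season_start_year)
  end <- season_end(season_start_year)
  bad <- !is.na(date) & (date < start | date > end)
  if (any(bad)) {
    stop(sprintf(
      "date(s) %s outside season %d window [%s, %s]",
      paste(format(date[bad]), collapse = ", "),
      season_start_year[1], format(start[1]), format(end[1])
    ))
  }
  as.integer(date - start) + 1L
}

#' @rdname to_ordinal
#' @param day integer day-of-season (1 = October 1).
#' @export
from_ordinal <- function(day, season_start_year) {
  n <- season_ndays(season_start_year)
  if (any(day < 1 | day > n)) {
    stop(sprintf("ordinal day outside [1, %d]", max(n)))
  }
  season_start(season_start_year) + (as.integer(day) - 1L)
}

season_start <- function(season_start_year) {
  as.Date(sprintf("%d-10-01", as.integer(season_start_year)))
}

season_end <- function(season_start_year) {
  as.Date(sprintf("%d-09-30", as.integer(season_start_year) + 1L))
}

#' Number of days in a nesting season
#'
#' 365, or 366 when the season contains February 29 (i.e. when the calendar
#' year following `season_start_year` is a leap year).
#'
#' @inheritParams to_ordinal
#' @export
season_ndays <- function(season_start_year) {
  as.integer(season_end(season_start_year) - season_start(season_start_year)) + 1L
}

#' Infer the season a calendar date belongs to
#'
#' Dates in October-December open a season; January-September dates belong to
#' the season opened the previous October.
#'
#' @inheritParams to_ordinal
#' @export
infer_season <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  ifelse(m >= 10L, y, y - 1L)
}

#' Season label like "2017-18"
#' @inheritParams to_ordinal
#' @export
season_label <- function(season_start_year) {
  sprintf("%d-%02d", season_start_year, (season_start_year + 1L) %% 100L)
}
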