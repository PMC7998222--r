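#' Daily temperature series on the back-extended day axis
#'
#' Container for one season of daily minimum / mean / maximum air
#' temperature driving thermal-time accumulation. Days are indexed on an
#' integer axis anchored to the *event year*: 1 January of the event year is
#' day 1, and days of the previous calendar year take indices <= 0
#' (1 September of the previous year is day -121). This back-extended axis
#' lets accumulation start dates fall in the previous autumn while event
#' dates stay ordinary day-of-year values.
#'
#' @param day Integer vector of strictly consecutive day indices.
#' @param tmin,tmean,tmax Numeric vectors of daily minimum, mean and maximum
#'   air temperature in degrees Celsius. Must satisfy
#'   `tmin <= tmean <= tmax` on every day.
#' @param year Event year the axis is anchored to (integer, optional but
#'   recommended; required when the series is written to file).
#'
#' @return An object of class `temperature_series`: a data frame with
#'   columns `day`, `tmin`, `tmean`, `tmax` and attribute `year`.
#' @examples
#' s <- temperature_series(1:10, tmin = 2, tmean = 8, tmax = 13, year = 2015)
#' s$tmean
#' @export
temperature_series <- function(day, tmin, tmean, tmax, year = NULL) {
  day <- as.integer(day)
  n <- length(day)
  tmin <- rep_len(as.numeric(tmin), n)
  tmean <- rep_len(as.numeric(tmean), n)
  tmax <- rep_len(as.numeric(tmax), n)
  if (n == 0L) stop("temperature series must contain at least one day")
  if (anyNA(day) || anyNA(tmin) || anyNA(tmean) || anyNA(tmax)) {
    stop("temperature series must not contain missing values")
  }
  if (n > 1L && any(diff(day) != 1L)) {
    gap <- day[which(diff(day) != 1L)[1]]
    stop(sprintf("day indices must be strictly consecutive (gap after day %d)", gap))
  }
  bad <- which(tmin > tmean | tmean > tmax)
  if (length(bad)) {
    stop(sprintf(
      "tmin <= tmean <= tmax violated on day %d (%.2f, %.2f, %.2f)",
      day[bad[1]], tmin[bad[1]], tmean[bad[1]], tmax[bad[1]]
    ))
  }
  out <- data.frame(day = day, tmin = tmin, tmean = tmean, tmax = tmax)
  attr(out, "year") <- if (is.null(year)) NA_integer_ else as.integer(year)
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Day index of a calendar date relative to an event year
#'
#' Maps a date onto the axis used by [temperature_series()]: 1 January of
#' `event_year` is day 1; earlier dates give indices <= 0. Leap years are
#' handled by calendar arithmetic, not a fixed 365-day year.
#'
#' @param date A `Date` vector (or string coercible with `as.Date`).
#' @param event_year The anchoring year.
#' @return Integer day indices.
#' @examples
#' day_index(as.Date("2014-09-01"), 2015) # -121
#' day_index(as.Date("2015-04-05"), 2015) # 95
#' @export
day_index <- function(date, event_year) {
  date <- as.Date(date)
  origin <- as.Date(sprintf("%d-01-01", as.integer(event_year)))
  as.integer(date - origin) + 1L
}

#' @export
print.temperature_series <- function(x, ...) {
  yr <- attr(x, "year")
  cat(sprintf(
    "<temperature_series> %d days [%d .. %d]%s\n",
    nrow(x), x$day[1], x$day[nrow(x)],
    if (is.na(yr)) "" else sprintf(", event year %d", yr)
  ))
  invisible(x)
}

# Restrict a series to days >= from (used when comparing dataset windows).
clip_series <- function(series, from) {
  keep <- series$day >= from
  if (!any(keep)) stop("clipping removed every day of the series")
  temperature_series(series$day[keep], series$tmin[keep],
                     series$tmean[keep], series$tmax[keep],
                     year = attr(series, "year"))
}
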