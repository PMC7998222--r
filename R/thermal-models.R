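#' Daily forcing-rate functions
#'
#' The three daily development-rate formulations used throughout the
#' package. All take the daily mean air temperature `x` (degC, vectorized)
#' and return a non-negative daily forcing rate:
#'
#' * `rf_gdd()` — growing degree-days: `max(0, x - tb)` above the base
#'   temperature `tb`, in degree-days.
#' * `rf_triangular()` — piecewise-linear triangular response over cardinal
#'   temperatures, 0 at or below `tmin_c`, rising linearly to 1 at `topt`,
#'   falling linearly back to 0 at `tmax_c`, 0 beyond. Dimensionless,
#'   in \[0, 1\].
#' * `rf_uniforc()` — UniFORC sigmoid `1 / (1 + exp(d * (x - e)))` for
#'   `x >= 0` and a hard 0 below 0 degC; `d < 0` is the sharpness and
#'   `e > 0` the mid-response temperature. Dimensionless, in \[0, 1).
#'
#' @param x Daily mean temperature(s), degC.
#' @param tb Base temperature, degC.
#' @param tmin_c,topt,tmax_c Cardinal temperatures, `tmin_c < topt < tmax_c`.
#' @param d Sigmoid sharpness, must be < 0.
#' @param e Sigmoid mid-response temperature, must be > 0.
#' @return Numeric vector of daily forcing rates, same length as `x`.
#' @examples
#' rf_gdd(10, tb = 5)                      # 5 degree-days
#' rf_triangular(12.5, 5, 20, 30)          # 0.5, halfway up the rising limb
#' rf_uniforc(10, d = -1, e = 10)          # 0.5 at the mid-response point
#' @export
rf_gdd <- function(x, tb) {
  pmax(0, x - tb)
}

#' @rdname rf_gdd
#' @export
rf_triangular <- function(x, tmin_c, topt, tmax_c) {
  if (!(tmin_c < topt && topt < tmax_c)) {
    stop("cardinal temperatures must satisfy tmin_c < topt < tmax_c")
  }
  out <- numeric(length(x))
  up <- x > tmin_c & x <= topt
  down <- x > topt & x < tmax_c
  out[up] <- (x[up] - tmin_c) / (topt - tmin_c)
  out[down] <- (x[down] - tmax_c) / (topt - tmax_c)
  out
}

#' @rdname rf_gdd
#' @export
rf_uniforc <- function(x, d, e) {
  if (!(d < 0)) stop("UniFORC sharpness d must be negative")
  if (!(e > 0)) stop("UniFORC mid-response temperature e must be positive")
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(d * (x[pos] - e)))
  out
}

#' Cumulative forcing from a start day
#'
#' Accumulates the daily forcing rate over the mean temperatures of a
#' [temperature_series()] from day `t0` (inclusive) through day `until`.
#'
#' @param series A [temperature_series()].
#' @param t0 First day included in the sum.
#' @param params A `pheno_params` object naming the rate model and its
#'   thresholds (`fstar` is ignored here).
#' @param until Last day of the sum; defaults to the end of the series.
#' @return A data frame with columns `day` and `forcing` (nondecreasing
#'   cumulative forcing, one row per day from `t0` to `until`).
#' @examples
#' s <- temperature_series(1:4, 8, 10, 13)
#' accumulate_forcing(s, t0 = 1, gdd_params(1, tb = 5))$forcing # 5 10 15 20
#' @export
accumulate_forcing <- function(series, t0, params, until = NULL) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(params, "pheno_params"))
  t0 <- as.integer(t0)
  first <- series$day[1]
  last <- series$day[nrow(series)]
  if (is.null(until)) until <- last
  until <- as.integer(until)
  if (t0 < first || t0 > last) {
    stop(sprintf("t0 = %d outside series coverage [%d, %d]", t0, first, last))
  }
  if (until < t0 || until > last) {
    stop(sprintf("until = %d outside [t0, %d]", until, last))
  }
  idx <- (t0 - first + 1L):(until - first + 1L)
  rates <- rate_for(params, series$tmean[idx])
  data.frame(day = series$day[idx], forcing = cumsum(rates))
}

#' Predict the day a phenophase is reached
#'
#' Runs the forcing accumulation of `params` over a temperature series and
#' returns the first day on which the cumulative forcing reaches the
#' critical total `fstar`. If the total is never reached within the series
#' the result carries `reached = FALSE` and an `NA` day (an explicit
#' "no event" signal, not an error).
#'
#' @param series A [temperature_series()] covering at least
#'   `params$t0 .. end of season`.
#' @param params A `pheno_params` object with finite `fstar > 0`.
#' @return An object of class `predicted_event`: a list with elements
#'   `day` (integer day index or `NA`), `forcing` (cumulative forcing at
#'   `day`, or at the series end when the event is not reached) and
#'   `reached` (logical).
#' @examples
#' s <- temperature_series(1:30, 8, 10, 13)
#' predict_event(s, gdd_params(t0 = 1, tb = 5, fstar = 50)) # day 10
#' @export
predict_event <- function(series, params) {
  if (is.na(params$fstar)) stop("params$fstar must be set to predict an event")
  acc <- accumulate_forcing(series, params$t0, params)
  hit <- which(acc$forcing >= params$fstar)
  if (length(hit)) {
    structure(list(day = acc$day[hit[1]], forcing = acc$forcing[hit[1]],
                   reached = TRUE),
              class = "predicted_event")
  } else {
    structure(list(day = NA_integer_, forcing = acc$forcing[nrow(acc)],
                   reached = FALSE),
              class = "predicted_event")
  }
}

#' @export
print.predicted_event <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("<predicted_event> day %d (forcing %.3f)\n", x$day, x$forcing))
  } else {
    cat(sprintf("<predicted_event> not reached (forcing %.3f at series end)\n",
                x$forcing))
  }
  invisible(x)
}
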