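#' Bundle meteorology and phenological observations
#'
#' A `pheno_dataset` ties together one [temperature_series()] per season
#' (keyed by event year) and a table of observed phenological events, one
#' row per variety x year x BBCH stage. Stage codes follow the BBCH scale
#' for grapevine: `"09"` = budburst (green shoot tips clearly visible),
#' `"61"` = beginning of flowering (10% of flower hoods fallen).
#'
#' @param met Named list of [temperature_series()], names = event years.
#' @param obs Data frame with columns `variety` (character), `year`
#'   (integer), `bbch` (`"09"` or `"61"`) and `doy` (observed event day on
#'   the day axis of the matching series, normally in 1..200).
#' @return An object of class `pheno_dataset`.
#' @export
pheno_dataset <- function(met, obs) {
  if (!is.list(met) || is.null(names(met)) || any(names(met) == "")) {
    stop("met must be a named list of temperature_series keyed by year")
  }
  for (nm in names(met)) {
    if (!inherits(met[[nm]], "temperature_series")) {
      stop("met[['", nm, "']] is not a temperature_series")
    }
  }
  obs <- as.data.frame(obs)
  need <- c("variety", "year", "bbch", "doy")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols)) {
    stop("obs is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  obs$variety <- as.character(obs$variety)
  obs$year <- as.integer(obs$year)
  obs$bbch <- format_bbch(obs$bbch)
  obs$doy <- as.integer(obs$doy)
  bad_stage <- setdiff(unique(obs$bbch), c("09", "61"))
  if (length(bad_stage)) {
    stop("unknown BBCH stage code(s): ", paste(bad_stage, collapse = ", "),
         " (supported: 09 budburst, 61 flowering)")
  }
  if (anyDuplicated(obs[c("variety", "year", "bbch")])) {
    stop("duplicate (variety, year, bbch) rows: one event per variety-year-stage")
  }
  missing_years <- setdiff(as.character(obs$year), names(met))
  if (length(missing_years)) {
    stop("observations reference years without meteorology: ",
         paste(missing_years, collapse = ", "))
  }
  structure(list(met = met, obs = obs[need]), class = "pheno_dataset")
}

format_bbch <- function(x) {
  x <- as.character(x)
  formatC(suppressWarnings(as.integer(x)), width = 2, flag = "0")
}

#' @export
print.pheno_dataset <- function(x, ...) {
  cat(sprintf(
    "<pheno_dataset> %d season(s), %d variety(ies), %d observation(s)\n",
    length(x$met), length(unique(x$obs$variety)), nrow(x$obs)
  ))
  invisible(x)
}

#' Subset a pheno_dataset by variety and/or stage
#'
#' @param data A [pheno_dataset()].
#' @param varieties Character vector of varieties to keep (default all).
#' @param bbch Stage code to keep (default all).
#' @return A [pheno_dataset()] restricted to the selection.
#' @export
subset_dataset <- function(data, varieties = NULL, bbch = NULL) {
  stopifnot(inherits(data, "pheno_dataset"))
  obs <- data$obs
  if (!is.null(varieties)) obs <- obs[obs$variety %in% varieties, , drop = FALSE]
  if (!is.null(bbch)) obs <- obs[obs$bbch %in% format_bbch(bbch), , drop = FALSE]
  if (nrow(obs) == 0L) stop("selection leaves no observations")
  pheno_dataset(data$met, obs)
}

# Flatten a dataset into the plain per-observation structure the fitting
# code iterates over: one entry per variety-year with the mean-temperature
# vector, its first day index, last day index and the observed event day.
# window_start (optional) clips each series to days >= window_start.
build_fit_data <- function(data, bbch, varieties = NULL, window_start = NULL) {
  stopifnot(inherits(data, "pheno_dataset"))
  obs <- data$obs[data$obs$bbch == format_bbch(bbch), , drop = FALSE]
  if (!is.null(varieties)) {
    obs <- obs[obs$variety %in% varieties, , drop = FALSE]
  }
  if (nrow(obs) == 0L) stop("no observations for BBCH stage ", bbch)
  entries <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    s <- data$met[[as.character(obs$year[i])]]
    if (!is.null(window_start)) s <- clip_series(s, window_start)
    entries[[i]] <- list(
      variety = obs$variety[i],
      year = obs$year[i],
      tm = s$tmean,
      first = s$day[1],
      last = s$day[nrow(s)],
      obs_day = obs$doy[i]
    )
  }
  entries
}
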