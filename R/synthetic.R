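#' Climate scenario for synthetic daily temperatures
#'
#' Parameters of the seeded temperature generator: a sinusoidal seasonal
#' cycle plus an AR(1) daily anomaly process and a per-year shift of the
#' annual mean. Defaults emulate a temperate, sub-humid NW-Iberian
#' wine-growing site with cold nights: annual mean 13.5 degC, seasonal
#' amplitude 7 degC with the coldest days in mid-January, daily anomalies
#' with sd 2.5 degC and lag-1 autocorrelation 0.75 (multi-day cold snaps
#' and warm spells, the feature that makes base temperatures
#' identifiable), a diurnal half-range of 5.5 degC and year-to-year shifts
#' of the annual mean with sd 1.0 degC.
#'
#' @param annual_mean Annual mean temperature, degC.
#' @param amplitude Seasonal half-amplitude, degC (> 0).
#' @param phase Phase shift in days: the seasonal term is
#'   `amplitude * sin(2 * pi * (day - phase) / 365.25)`. The default 106
#'   puts the minimum near 15 January.
#' @param noise_sd Marginal sd of the daily anomaly, degC (>= 0).
#' @param diurnal_half_range Half-distance between daily minimum and
#'   maximum, degC (> 0): `tmin = tmean - h`, `tmax = tmean + h`.
#' @param interannual_sd Sd of the per-year shift of the annual mean, degC.
#' @param ar1 AR(1) coefficient of the anomaly process in \[0, 1); 0
#'   gives white noise. The marginal anomaly sd stays `noise_sd`.
#' @param seed Integer seed; all generated series are reproducible given
#'   the scenario.
#' @return A list of class `climate_scenario`.
#' @export
climate_scenario <- function(annual_mean = 13.5, amplitude = 7,
                             phase = 106, noise_sd = 2.5,
                             diurnal_half_range = 5.5,
                             interannual_sd = 1.0, ar1 = 0.75, seed = 42L) {
  stopifnot(amplitude > 0, noise_sd >= 0, diurnal_half_range > 0,
            interannual_sd >= 0, ar1 >= 0, ar1 < 1)
  structure(
    list(annual_mean = annual_mean, amplitude = amplitude, phase = phase,
         noise_sd = noise_sd, diurnal_half_range = diurnal_half_range,
         interannual_sd = interannual_sd, ar1 = ar1,
         seed = as.integer(seed)),
    class = "climate_scenario"
  )
}

#' Generating truth for one synthetic variety
#'
#' Bundles a variety name with the forcing-model parameters that generate
#' its budburst (BBCH 09) and flowering (BBCH 61) dates, the sd of the
#' observation noise added to the event date (days), and an optional field
#' visit interval: with `visit_interval > 0` the observed date is snapped
#' forward to the next visit day, emulating discrete field inspections.
#'
#' @param variety Variety name (free text).
#' @param budburst,flowering `pheno_params` with `fstar` set.
#' @param obs_noise_sd Sd of the (rounded) Gaussian noise on the event day.
#' @param visit_interval 0 for exact dates, or a visit cadence of 3-7 days.
#' @return A list of class `variety_truth`.
#' @export
variety_truth <- function(variety, budburst, flowering, obs_noise_sd = 2,
                          visit_interval = 0) {
  stopifnot(inherits(budburst, "pheno_params"),
            inherits(flowering, "pheno_params"),
            obs_noise_sd >= 0,
            visit_interval == 0 || (visit_interval >= 3 && visit_interval <= 7))
  if (is.na(budburst$fstar) || is.na(flowering$fstar)) {
    stop("generating params must have fstar set")
  }
  structure(
    list(variety = as.character(variety), budburst = budburst,
         flowering = flowering, obs_noise_sd = obs_noise_sd,
         visit_interval = visit_interval),
    class = "variety_truth"
  )
}

#' Default synthetic varieties
#'
#' Four grapevine varieties whose generating GDD parameters are seeded from
#' published per-variety fits for this region (start day, base temperature
#' and total heat requirement for budburst and flowering), so that default
#' synthetic fixtures land budburst around day-of-year 90-100 and flowering
#' around 145-160 under the default [climate_scenario()].
#'
#' @param obs_noise_sd Observation noise sd passed to every variety.
#' @param visit_interval Visit cadence passed to every variety.
#' @return Named list of [variety_truth()] objects.
#' @export
default_varieties <- function(obs_noise_sd = 2, visit_interval = 0) {
  defs <- list(
    Albarino   = list(bb = c(62, 8, 75.141),  fl = c(27, 7, 533)),
    Godello    = list(bb = c(49, 5, 208.931), fl = c(52, 6, 626.092)),
    Loureira   = list(bb = c(79, 10, 18.616), fl = c(72, 6, 587.035)),
    Treixadura = list(bb = c(49, 5, 228.503), fl = c(52, 7, 575.441))
  )
  out <- lapply(names(defs), function(v) {
    p <- defs[[v]]
    variety_truth(
      v,
      budburst = gdd_params(p$bb[1], p$bb[2], p$bb[3]),
      flowering = gdd_params(p$fl[1], p$fl[2], p$fl[3]),
      obs_noise_sd = obs_noise_sd, visit_interval = visit_interval
    )
  })
  stats::setNames(out, names(defs))
}

#' Generate one season of synthetic daily temperatures
#'
#' Builds a [temperature_series()] covering 1 September of the previous
#' year through 31 August of `year` (calendar-aware, so leap years have
#' their extra day). The daily mean is
#' `annual_mean + year_shift + amplitude * sin(2*pi*(day - phase)/365.25)`
#' plus (optionally AR(1)) Gaussian noise; `tmin`/`tmax` are the mean
#' minus/plus the diurnal half-range. The same scenario and year always
#' produce the same series.
#'
#' @param scenario A [climate_scenario()].
#' @param year Event year.
#' @return A [temperature_series()].
#' @export
generate_temperature_series <- function(scenario, year) {
  stopifnot(inherits(scenario, "climate_scenario"))
  year <- as.integer(year)
  from <- as.Date(sprintf("%d-09-01", year - 1L))
  to <- as.Date(sprintf("%d-08-31", year))
  days <- day_index(seq(from, to, by = "day"), year)
  withr::with_seed(derive_seed(scenario$seed, year), {
    shift <- stats::rnorm(1, 0, scenario$interannual_sd)
    eps <- stats::rnorm(length(days), 0, scenario$noise_sd)
    if (scenario$ar1 > 0 && length(days) > 1) {
      for (i in 2:length(eps)) {
        eps[i] <- scenario$ar1 * eps[i - 1] +
          sqrt(1 - scenario$ar1^2) * eps[i]
      }
    }
    tmean <- scenario$annual_mean + shift +
      scenario$amplitude * sin(2 * pi * (days - scenario$phase) / 365.25) +
      eps
    temperature_series(days,
                       tmin = tmean - scenario$diurnal_half_range,
                       tmean = tmean,
                       tmax = tmean + scenario$diurnal_half_range,
                       year = year)
  })
}

#' Generate a synthetic multi-variety observation campaign
#'
#' For every year, simulates one site temperature series shared by all
#' varieties; for every variety and phenophase, runs the generating model's
#' event prediction, adds rounded Gaussian observation noise, and (when the
#' variety's `visit_interval` > 0) snaps the date forward to the next field
#' visit day. Emits both budburst (BBCH 09) and flowering (BBCH 61) events.
#'
#' @param scenario A [climate_scenario()].
#' @param truths Named list of [variety_truth()]s
#'   (default [default_varieties()]).
#' @param years Integer vector of event years (default 2008-2019, the
#'   12-season design).
#' @return A [pheno_dataset()]; the scenario, truths and years are attached
#'   as attribute `manifest`.
#' @examples
#' \donttest{
#' d <- generate_observations(climate_scenario(seed = 7), years = 2008:2010)
#' d$obs
#' }
#' @export
generate_observations <- function(scenario = climate_scenario(),
                                  truths = default_varieties(),
                                  years = 2008:2019) {
  stopifnot(inherits(scenario, "climate_scenario"), length(truths) >= 1,
            length(years) >= 1)
  met <- stats::setNames(
    lapply(years, function(y) generate_temperature_series(scenario, y)),
    as.character(years)
  )
  rows <- list()
  for (y in years) {
    s <- met[[as.character(y)]]
    for (tr in truths) {
      for (stage in c("09", "61")) {
        pars <- if (stage == "09") tr$budburst else tr$flowering
        ev <- predict_event(s, pars)
        if (!ev$reached) {
          stop(sprintf(
            "generating params never trigger BBCH %s for %s in %d under this scenario",
            stage, tr$variety, y
          ))
        }
        doy <- ev$day
        withr::with_seed(
          derive_seed(scenario$seed,
                      y * 1000L + match(stage, c("09", "61")) * 100L +
                        utf8_key(tr$variety)),
          {
            if (tr$obs_noise_sd > 0) {
              doy <- doy + round(stats::rnorm(1, 0, tr$obs_noise_sd))
            }
            if (tr$visit_interval > 0) {
              anchor <- sample.int(tr$visit_interval, 1) - 1L
              doy <- doy + (anchor - doy) %% tr$visit_interval
            }
          }
        )
        rows[[length(rows) + 1L]] <- data.frame(
          variety = tr$variety, year = y, bbch = stage, doy = as.integer(doy)
        )
      }
    }
  }
  out <- pheno_dataset(met, do.call(rbind, rows))
  attr(out, "manifest") <- list(scenario = scenario, truths = truths,
                                years = years)
  out
}

# small deterministic hash of a variety name for seed derivation
utf8_key <- function(x) {
  sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) %% 997L
}
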