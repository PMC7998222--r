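# Shared fixtures: small deterministic series and datasets built in code.

# constant-mean-temperature series over days 1..n
const_series <- function(n, tmean, year = 2000) {
  temperature_series(1:n, tmin = tmean - 3, tmean = tmean, tmax = tmean + 3,
                     year = year)
}

# a short anneal schedule for unit tests (acceptance tests use defaults)
small_schedule <- function() {
  sa_schedule(iters_per_temp = 50, max_temps = 20, patience = 5)
}

# dataset of `years` seasons of constant temperature with one variety whose
# observed day is the exact GDD event day (offset added for imperfection)
const_gdd_dataset <- function(years = 3, tmean = 10, tb = 5, t0 = 1,
                              fstar = 50, offset = 0, variety = "V",
                              n_days = 200) {
  yr <- seq(2001, length.out = years)
  met <- stats::setNames(
    lapply(yr, function(y) const_series(n_days, tmean, year = y)), yr)
  pars <- gdd_params(t0, tb, fstar)
  obs <- do.call(rbind, lapply(yr, function(y) {
    ev <- predict_event(met[[as.character(y)]], pars)
    data.frame(variety = variety, year = y, bbch = "09",
               doy = ev$day + offset)
  }))
  pheno_dataset(met, obs)
}

# small noiseless synthetic campaign for fitting tests
synth_dataset <- function(seed = 11, noise_sd = 0, years = 2008:2019,
                          truths = NULL) {
  if (is.null(truths)) truths <- default_varieties(obs_noise_sd = noise_sd)
  generate_observations(climate_scenario(seed = seed), truths, years)
}

one_variety_truth <- function(noise_sd = 0, t0 = 49, tb = 5,
                              fstar = 228.503) {
  list(Treixadura = variety_truth(
    "Treixadura",
    budburst = gdd_params(t0, tb, fstar),
    flowering = gdd_params(52, 7, 575.441),
    obs_noise_sd = noise_sd
  ))
}
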