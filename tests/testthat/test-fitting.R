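test_that("objective is the residual sum of squares in days", {
  d <- const_gdd_dataset(years = 3, tmean = 10, tb = 5, fstar = 50)
  perfect <- gdd_params(1, 5, 50)
  expect_equal(objective(perfect, d, "09"), 0)

  # every event predicted 2 days late -> n * 4
  late <- const_gdd_dataset(years = 12, tmean = 10, tb = 5, fstar = 50,
                            offset = -2)
  expect_equal(objective(perfect, late, "09"), 12 * 4)

  # base temperature above every temperature: finite penalty at series end
  frozen <- gdd_params(1, 50, 50)
  pen <- objective(frozen, d, "09")
  expect_true(is.finite(pen))
  expect_equal(pen, 3 * (200 - 10)^2) # predicted at day 200, observed day 10
})

test_that("estimate_fstar profiles the critical total from observed days", {
  # single year, constant rate 5/day, observed 10 days after t0
  d1 <- const_gdd_dataset(years = 1, tmean = 10, tb = 5, fstar = 50)
  expect_equal(estimate_fstar(gdd_params(1, 5), d1, "09"), 50)

  # two years with accumulations 40 and 60 at the observed dates -> mean 50
  met <- list(`2001` = const_series(100, 10, 2001),
              `2002` = const_series(100, 10, 2002))
  obs <- data.frame(variety = "V", year = c(2001, 2002), bbch = "09",
                    doy = c(8, 12))
  d2 <- pheno_dataset(met, obs)
  expect_equal(estimate_fstar(gdd_params(1, 5), d2, "09"), 50)

  # noiseless forward simulation recovers the generating fstar exactly
  d3 <- const_gdd_dataset(years = 4, tmean = 10, tb = 5, fstar = 50)
  expect_equal(estimate_fstar(gdd_params(1, 5), d3, "09"), 50)

  # zero-forcing year excluded with a warning; all-zero is an error
  met4 <- list(`2001` = const_series(100, 10, 2001),
               `2002` = const_series(100, 2, 2002))
  d4 <- pheno_dataset(met4, data.frame(variety = "V", year = 2001:2002,
                                       bbch = "09", doy = c(10, 10)))
  expect_warning(f <- estimate_fstar(gdd_params(1, 5), d4, "09"),
                 "zero forcing")
  expect_equal(f, 50)
  cold <- pheno_dataset(list(`2001` = const_series(100, 2, 2001)),
                        data.frame(variety = "V", year = 2001,
                                   bbch = "09", doy = 10))
  expect_error(estimate_fstar(gdd_params(1, 5), cold, "09"), "undefined")
})

test_that("profiled objective refits noiseless synthetic data exactly", {
  d <- synth_dataset(seed = 31, noise_sd = 0, years = 2008:2015,
                     truths = one_variety_truth())
  res <- profiled_objective(gdd_params(49, 5), d, "09")
  expect_equal(res$loss, 0)
  expect_equal(res$predictions$predicted, res$predictions$observed)
})

test_that("annealing is reproducible and rejects an empty space", {
  d <- synth_dataset(seed = 13, noise_sd = 2, years = 2008:2013,
                     truths = one_variety_truth(noise_sd = 2))
  f1 <- anneal(param_space("gdd"), d, "09", seed = 4, starts = 2,
               schedule = small_schedule(), window_start = 1)
  f2 <- anneal(param_space("gdd"), d, "09", seed = 4, starts = 2,
               schedule = small_schedule(), window_start = 1)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$ranges, f2$ranges)

  bad <- param_space("gdd", overrides = list(tb = c(10, 5)))
  expect_error(anneal(bad, d, "09"), "empty search space")
})

test_that("annealing never ends worse than its own best start and finds zero loss on noiseless data", {
  d <- synth_dataset(seed = 17, noise_sd = 0, years = 2008:2015,
                     truths = one_variety_truth())
  f <- anneal(param_space("gdd"), d, "09", seed = 2, starts = 4,
              schedule = small_schedule(), window_start = 1)
  expect_equal(f$loss, 0)
  expect_equal(f$metrics$eff, 1)
  expect_true(all(f$start_losses >= f$loss))
})

test_that("annealing matches exhaustive grid search on a discretized problem", {
  d <- synth_dataset(seed = 23, noise_sd = 2, years = 2008:2013,
                     truths = one_variety_truth(noise_sd = 2))
  space <- param_space("gdd", overrides = list(t0 = c(30, 70), tb = c(2, 10)))
  space$step[space$name == "tb"] <- 1
  grid <- expand.grid(t0 = 30:70, tb = 2:10)
  grid_best <- min(vapply(seq_len(nrow(grid)), function(i) {
    profiled_objective(gdd_params(grid$t0[i], grid$tb[i]), d, "09")$loss
  }, 1))
  hits <- 0L
  for (s in 1:5) {
    f <- anneal(space, d, "09", seed = s, starts = 2,
                schedule = small_schedule())
    if (abs(f$loss - grid_best) <= 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("per-variety calibration skips short records and is data-driven", {
  d <- synth_dataset(seed = 41, noise_sd = 0, years = 2008:2013)
  # two varieties sharing identical generating data get identical fits
  obs <- d$obs
  twin <- obs[obs$variety == "Treixadura", ]
  twin$variety <- "Clone"
  short <- obs[obs$variety == "Loureira" & obs$year == 2008, ]
  keep <- obs[obs$variety %in% c("Treixadura", "Godello"), ]
  d2 <- pheno_dataset(d$met, rbind(keep, twin, short))
  expect_warning(
    fits <- calibrate_per_variety(d2, "09", seed = 3, starts = 2,
                                  schedule = small_schedule(),
                                  window_start = 1),
    "fewer than 2 years"
  )
  expect_setequal(names(fits), c("Treixadura", "Godello", "Clone"))
  expect_identical(fits$Clone$params, fits$Treixadura$params)
  expect_identical(fits$Clone$metrics, fits$Treixadura$metrics)
})

test_that("external validation freezes the donor and is exact on matched data", {
  d <- synth_dataset(seed = 19, noise_sd = 0, years = 2008:2014)
  fit <- anneal(param_space("gdd"), d, "09", varieties = "Treixadura",
                seed = 6, starts = 3, schedule = small_schedule(),
                window_start = 1)
  # self-validation reproduces estimation metrics bit-for-bit
  self <- external_validate(fit, d, "09", varieties = "Treixadura")
  expect_identical(self$metrics, fit$metrics)
  expect_identical(self$predictions, fit$predictions)

  # Godello shares the generating model family; a recipient simulated with
  # the donor's own parameters validates perfectly at zero noise
  truths <- list(
    A = variety_truth("A", gdd_params(49, 5, 228.503),
                      gdd_params(52, 7, 575.441), obs_noise_sd = 0),
    B = variety_truth("B", gdd_params(49, 5, 228.503),
                      gdd_params(52, 7, 575.441), obs_noise_sd = 0),
    C = variety_truth("C", gdd_params(49, 10, 228.503),
                      gdd_params(52, 7, 575.441), obs_noise_sd = 0)
  )
  dd <- synth_dataset(seed = 19, years = 2008:2014, truths = truths)
  fitA <- anneal(param_space("gdd"), dd, "09", varieties = "A",
                 seed = 6, starts = 3, schedule = small_schedule(),
                 window_start = 1)
  same <- external_validate(fitA, dd, "09", varieties = "B")
  expect_equal(same$metrics$eff, 1)
  # a recipient generated with a 5 degC higher base temperature fits worse
  mismatch <- external_validate(fitA, dd, "09", varieties = "C")
  expect_lt(mismatch$metrics$eff, same$metrics$eff)
})

test_that("validation matrix has frozen off-diagonals and an estimation diagonal", {
  d <- synth_dataset(seed = 29, noise_sd = 2, years = 2008:2013)
  fits <- calibrate_per_variety(d, "09", seed = 2, starts = 2,
                                schedule = small_schedule(),
                                window_start = 1)
  vm <- validation_matrix(fits, d, "09")
  expect_equal(dim(vm$eff), c(4, 4))
  for (v in names(fits)) {
    expect_identical(vm$eff[v, v], fits[[v]]$metrics$eff)
    expect_identical(vm$rmse[v, v], fits[[v]]$metrics$rmse)
  }
  expect_equal(nrow(vm$table), 16)
  expect_setequal(unique(vm$table$phase), c("estimation", "validation"))
})

test_that("the pooled global fit uses every variety-year", {
  truths <- default_varieties(obs_noise_sd = 0)
  # all varieties generated with identical parameters: no pooling loss
  for (v in names(truths)) {
    truths[[v]]$budburst <- gdd_params(49, 5, 228.503)
  }
  d <- synth_dataset(seed = 37, years = 2008:2013, truths = truths)
  g <- fit_global(d, "09", seed = 8, starts = 3,
                  schedule = small_schedule(), window_start = 1)
  expect_equal(g$metrics$n, 4 * 6)
  expect_equal(g$metrics$eff, 1)
  expect_equal(g$loss, 0)
})

test_that("window comparison prefers January unless autumn forcing is real", {
  # truth starts accumulating within the year: both windows can be exact,
  # January wins by the tie/selection rule
  d_jan <- synth_dataset(seed = 43, noise_sd = 0, years = 2008:2013,
                         truths = one_variety_truth())
  cw <- compare_start_windows(d_jan, "09", seed = 5, starts = 2,
                              schedule = small_schedule())
  expect_equal(cw$selected, "jan")
  expect_equal(cw$jan$metrics$eff, 1)

  # truth starts in the previous autumn: only the September window can
  # reproduce it exactly
  autumn <- list(V = variety_truth(
    "V", budburst = gdd_params(-50, 0, 1300),
    flowering = gdd_params(52, 7, 575.441), obs_noise_sd = 0))
  d_sep <- synth_dataset(seed = 43, years = 2008:2013, truths = autumn)
  cw2 <- compare_start_windows(d_sep, "09", seed = 5, starts = 4,
                               schedule = sa_schedule(iters_per_temp = 100,
                                                      max_temps = 30,
                                                      patience = 8))
  expect_equal(cw2$sep$metrics$eff, 1)
  expect_gt(cw2$sep$metrics$eff, cw2$jan$metrics$eff)
  expect_equal(cw2$selected, "sep")
})

test_that("model selection prefers the simplest near-equal model", {
  fake <- function(eff) list(metrics = list(eff = eff))
  expect_equal(select_model(list(gdd = fake(0.95), triangular = fake(0.955))),
               "gdd")
  expect_equal(select_model(list(gdd = fake(0.90), triangular = fake(0.955))),
               "triangular")
  expect_equal(select_model(list(gdd = fake(0.95), uniforc = fake(0.95),
                                 triangular = fake(0.95))), "gdd")
})
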