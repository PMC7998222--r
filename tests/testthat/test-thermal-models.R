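test_that("GDD rate is the linear excess above the base temperature", {
  expect_identical(rf_gdd(10, tb = 5), 5)
  expect_identical(rf_gdd(4, tb = 5), 0)
  expect_identical(rf_gdd(5, tb = 5), 0)
  expect_equal(rf_gdd(c(-2, 5, 9.5), tb = 5), c(0, 0, 4.5))
})

test_that("triangular rate is piecewise linear over the cardinal temperatures", {
  expect_equal(rf_triangular(20, 5, 20, 30), 1)    # apex
  expect_equal(rf_triangular(5, 5, 20, 30), 0)     # lower cardinal
  expect_equal(rf_triangular(12.5, 5, 20, 30), 0.5) # rising-limb midpoint
  expect_equal(rf_triangular(25, 5, 20, 30), 0.5)  # falling limb
  expect_equal(rf_triangular(30, 5, 20, 30), 0)    # upper cardinal
  expect_equal(rf_triangular(c(-10, 50), 5, 20, 30), c(0, 0))
  expect_error(rf_triangular(10, 20, 5, 30), "cardinal")
})

test_that("UniFORC rate is the sigmoid with a hard zero below 0 degC", {
  expect_equal(rf_uniforc(10, d = -1, e = 10), 0.5)
  expect_equal(rf_uniforc(-1, d = -1, e = 10), 0)
  expect_equal(rf_uniforc(12, d = -1, e = 10), 1 / (1 + exp(-2)))
  expect_error(rf_uniforc(10, d = 1, e = 10), "negative")
  expect_error(rf_uniforc(10, d = -1, e = -2), "positive")
})

test_that("rate functions are bounded and monotone where the model says so", {
  x <- seq(-15, 55, by = 0.25)
  g <- rf_gdd(x, tb = 6)
  u <- rf_uniforc(x, d = -0.4, e = 12)
  tr <- rf_triangular(x, 4, 22, 35)
  expect_true(all(g >= 0) && all(u >= 0) && all(tr >= 0))
  expect_true(all(u <= 1) && all(tr <= 1))
  expect_true(all(diff(g) >= 0))
  expect_true(all(diff(u) >= 0))
  apex <- which.max(x >= 22)
  expect_true(all(diff(tr[1:apex]) >= 0))
  expect_true(all(diff(tr[apex:length(x)]) <= 0))
})

test_that("forcing accumulates from t0 inclusive over mean temperatures", {
  s <- const_series(10, 10)
  acc <- accumulate_forcing(s, t0 = 1, gdd_params(1, tb = 5), until = 4)
  expect_equal(acc$forcing, c(5, 10, 15, 20))
  one <- accumulate_forcing(s, t0 = 3, gdd_params(3, tb = 5), until = 3)
  expect_equal(nrow(one), 1L)
  expect_equal(one$forcing, rf_gdd(s$tmean[3], 5))
  cold <- accumulate_forcing(const_series(10, 2),
                             1, triangular_params(1, 5, 20, 30))
  expect_true(all(cold$forcing == 0))
  expect_error(accumulate_forcing(s, t0 = 99, gdd_params(99, 5)),
               "coverage")
})

test_that("predict_event returns the first day the threshold is crossed", {
  s <- const_series(30, 10)
  ev <- predict_event(s, gdd_params(1, tb = 5, fstar = 50))
  expect_true(ev$reached)
  expect_identical(ev$day, 10L)
  expect_equal(ev$forcing, 50)

  tiny <- predict_event(s, gdd_params(7, tb = 5, fstar = 1e-4))
  expect_identical(tiny$day, 7L)

  never <- predict_event(const_series(30, 4), gdd_params(1, 5, fstar = 1))
  expect_false(never$reached)
  expect_identical(never$day, NA_integer_)
})

test_that("predict_event matches a brute-force day-by-day scan", {
  # oracle: walk forward one day at a time, accumulating with a scalar sum
  scan_oracle <- function(series, params) {
    total <- 0
    for (i in which(series$day == params$t0):nrow(series)) {
      total <- total + rate_for_scalar(params, series$tmean[i])
      if (total >= params$fstar) return(series$day[i])
    }
    NA_integer_
  }
  rate_for_scalar <- function(p, x) {
    switch(p$model,
      gdd = max(0, x - p$tb),
      triangular = {
        if (x <= p$tmin_c || x >= p$tmax_c) 0
        else if (x <= p$topt) (x - p$tmin_c) / (p$topt - p$tmin_c)
        else (x - p$tmax_c) / (p$topt - p$tmax_c)
      },
      uniforc = if (x < 0) 0 else 1 / (1 + exp(p$d * (x - p$e)))
    )
  }
  withr::with_seed(404, {
    for (rep in 1:20) {
      n <- sample(60:150, 1)
      tm <- runif(n, -2, 25)
      s <- temperature_series(1:n, tm - 2, tm, tm + 2)
      params <- switch(sample(3, 1),
        gdd_params(sample(1:10, 1), runif(1, 0, 10), runif(1, 5, 400)),
        triangular_params(sample(1:10, 1), 2, 18, 30, runif(1, 0.5, 40)),
        uniforc_params(sample(1:10, 1), -runif(1, 0.2, 3),
                       runif(1, 8, 18), runif(1, 0.5, 40))
      )
      ev <- predict_event(s, params)
      expect_identical(ev$day, scan_oracle(s, params))
    }
  })
})

test_that("predicted day responds monotonically to warming, fstar and t0", {
  withr::with_seed(99, {
    for (rep in 1:12) {
      n <- 200
      tm <- 8 + 8 * sin(2 * pi * ((1:n) - 106) / 365.25) + rnorm(n, 0, 1.5)
      s <- temperature_series(1:n, tm - 3, tm, tm + 3)
      warm <- temperature_series(1:n, tm - 2, tm + 1, tm + 4)
      for (params in list(gdd_params(5, 5, 120),
                          uniforc_params(5, -0.5, 10, 25))) {
        base <- predict_event(s, params)
        up <- predict_event(warm, params)
        if (base$reached) {
          expect_true(up$reached)
          expect_lte(up$day, base$day)
        }
        # nondecreasing in fstar
        p_hi <- params; p_hi$fstar <- params$fstar * 1.5
        hi <- predict_event(s, p_hi)
        if (hi$reached) expect_gte(hi$day, base$day)
        # nondecreasing in t0
        p_late <- params; p_late$t0 <- params$t0 + 20L
        late <- predict_event(s, p_late)
        if (late$reached) expect_gte(late$day, base$day)
      }
    }
  })
})

test_that("temperature_series validates its invariants", {
  expect_error(temperature_series(c(1, 2, 4), 0, 5, 9), "consecutive")
  expect_error(temperature_series(1:3, 10, 5, 9), "violated")
  expect_error(temperature_series(1:3, 0, c(5, NA, 5), 9), "missing")
  s <- temperature_series(-121:243, 0, 5, 9, year = 2015)
  expect_equal(nrow(s), 365)
})

test_that("day_index anchors 1 Jan of the event year and respects leap years", {
  expect_identical(day_index(as.Date("2015-01-01"), 2015), 1L)
  expect_identical(day_index(as.Date("2014-09-01"), 2015), -121L)
  expect_identical(day_index(as.Date("2014-12-31"), 2015), 0L)
  expect_identical(day_index(as.Date("2016-08-31"), 2016), 244L) # leap year
  expect_identical(day_index(as.Date("2015-08-31"), 2015), 243L)
})
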