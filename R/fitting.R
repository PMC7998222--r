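#' Default parameter search space
#'
#' Bounds and proposal granularity for the free (threshold) parameters of
#' each model. The start day `t0` is searched on an integer grid; the
#' remaining thresholds are continuous. The critical forcing total `fstar`
#' is not part of the search space: it is profiled out analytically inside
#' every objective evaluation (see [estimate_fstar()]).
#'
#' Default bounds: `t0` in 1..150 for the January window or -121..150 for
#' the window opening on 1 September of the previous year; base temperature
#' `tb` in 0..30 degC; cardinal temperatures `tmin_c` 0..15, `topt` 5..30,
#' `tmax_c` 15..50 degC; sigmoid sharpness `d` in -40..-0.01 and
#' mid-response temperature `e` in 5..25 degC.
#'
#' @param model `"gdd"`, `"triangular"` or `"uniforc"`.
#' @param window `"jan"` (accumulation can start no earlier than 1 January
#'   of the event year) or `"sep"` (start may fall back to 1 September of
#'   the previous year).
#' @param overrides Optional named list `name = c(lower, upper)` replacing
#'   default bounds.
#' @return A data frame of class `param_space` with columns `name`,
#'   `lower`, `upper`, `step` (0 = continuous, > 0 = grid spacing) and
#'   attributes `model`, `window`.
#' @examples
#' param_space("gdd")
#' param_space("gdd", overrides = list(tb = c(0, 15)))
#' @export
param_space <- function(model = c("gdd", "triangular", "uniforc"),
                        window = c("jan", "sep"), overrides = NULL) {
  model <- match.arg(model)
  window <- match.arg(window)
  t0_lower <- if (window == "jan") 1 else -121
  rows <- switch(model,
    gdd = data.frame(
      name = c("t0", "tb"),
      lower = c(t0_lower, 0), upper = c(150, 30), step = c(1, 0)
    ),
    triangular = data.frame(
      name = c("t0", "tmin_c", "topt", "tmax_c"),
      lower = c(t0_lower, 0, 5, 15), upper = c(150, 15, 30, 50),
      step = c(1, 0, 0, 0)
    ),
    uniforc = data.frame(
      name = c("t0", "d", "e"),
      lower = c(t0_lower, -40, 5), upper = c(150, -0.01, 25),
      step = c(1, 0, 0)
    )
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, rows$name)
      if (is.na(i)) stop("unknown parameter in overrides: ", nm)
      rows$lower[i] <- overrides[[nm]][1]
      rows$upper[i] <- overrides[[nm]][2]
    }
  }
  structure(rows, model = model, window = window,
            class = c("param_space", "data.frame"))
}

check_space <- function(space) {
  if (!inherits(space, "param_space")) stop("space must be a param_space")
  bad <- which(space$lower > space$upper)
  if (length(bad)) {
    stop("empty search space: lower > upper for parameter ",
         space$name[bad[1]])
  }
  invisible(TRUE)
}

#' Simulated-annealing schedule
#'
#' Tunables of the Metropolis annealer. Cooling is geometric
#' (`T_{k+1} = cooling * T_k`) with `iters_per_temp` proposals per
#' temperature level. The initial temperature is calibrated from a short
#' random walk so that roughly 80% of uphill moves are accepted at the
#' start (override with `t_init`). The search stops after `max_temps`
#' levels, after `patience` levels without improvement of the best loss, or
#' immediately when the loss reaches zero. Proposals change one parameter
#' at a time: integer parameters move by 1-3 grid steps, continuous ones by
#' a Gaussian step (`prop_sd` units), with reflection at the bounds. A
#' deterministic coordinate-descent polish (at most `polish_budget`
#' evaluations) refines the best point found.
#'
#' @param cooling Geometric cooling factor in (0, 1).
#' @param iters_per_temp Proposals per temperature level.
#' @param max_temps Maximum number of temperature levels.
#' @param patience Levels without improvement before stopping.
#' @param t_init Initial temperature, or `NULL` to calibrate.
#' @param prop_sd Gaussian proposal sd for continuous parameters.
#' @param polish Run the deterministic polish after annealing.
#' @param polish_budget Maximum objective evaluations spent in the polish.
#' @return A list of class `sa_schedule`.
#' @export
sa_schedule <- function(cooling = 0.95, iters_per_temp = 200, max_temps = 60,
                        patience = 10, t_init = NULL, prop_sd = 1,
                        polish = TRUE, polish_budget = 400) {
  stopifnot(cooling > 0, cooling < 1, iters_per_temp >= 1, max_temps >= 1)
  structure(
    list(cooling = cooling, iters_per_temp = iters_per_temp,
         max_temps = max_temps, patience = patience, t_init = t_init,
         prop_sd = prop_sd, polish = polish, polish_budget = polish_budget),
    class = "sa_schedule"
  )
}

# ---------------------------------------------------------------------------
# Objective core. All fitting-time arithmetic funnels through these two
# functions so that estimation metrics, external validation and user-facing
# prediction agree bit-for-bit.

rate_theta <- function(model, theta, x) {
  switch(model,
    gdd = rf_gdd(x, theta[["tb"]]),
    triangular = rf_triangular(x, theta[["tmin_c"]], theta[["topt"]],
                               theta[["tmax_c"]]),
    uniforc = rf_uniforc(x, theta[["d"]], theta[["e"]])
  )
}

# Cumulative forcing per entry from t0; forcing at observed day and at the
# day before it (0 when the observed day precedes t0 or any forcing).
forcing_state <- function(model, theta, fd) {
  t0 <- as.integer(theta[["t0"]])
  n <- length(fd)
  cums <- vector("list", n)
  fobs <- numeric(n)
  fprev <- numeric(n)
  for (i in seq_len(n)) {
    e <- fd[[i]]
    if (t0 < e$first || t0 > e$last) {
      stop(sprintf("t0 = %d outside meteorology coverage [%d, %d] for %s %d",
                   t0, e$first, e$last, e$variety, e$year))
    }
    pos0 <- t0 - e$first + 1L
    cum <- cumsum(rate_theta(model, theta, e$tm[pos0:length(e$tm)]))
    obs_pos <- e$obs_day - t0 + 1L
    cums[[i]] <- cum
    fobs[i] <- if (obs_pos >= 1L) cum[min(obs_pos, length(cum))] else 0
    fprev[i] <- if (obs_pos >= 2L) cum[min(obs_pos, length(cum)) - 1L] else 0
  }
  list(t0 = t0, cums = cums, fobs = fobs, fprev = fprev)
}

# Profile fstar out of the search: mean of the per-entry cumulative forcing
# at the observed event day, over entries with positive forcing there. When
# an interval of fstar values reproduces every contributing observed day
# exactly (max fprev < min fobs) and the mean falls outside it, the
# estimate snaps to min(fobs), the largest exactly-fitting value. This
# keeps the estimator deterministic and makes noiseless data refit with
# zero residual.
fstar_from_state <- function(state) {
  ok <- state$fobs > 0
  if (!any(ok)) {
    return(list(fstar = NA_real_, excluded = seq_along(state$fobs)))
  }
  fobs <- state$fobs[ok]
  fmean <- mean(fobs)
  lo <- max(state$fprev[ok])
  hi <- min(fobs)
  fstar <- if (lo < hi && (fmean > hi || fmean <= lo)) hi else fmean
  list(fstar = fstar, excluded = which(!ok))
}

# Predicted event day per entry: first day with cumulative forcing >= fstar,
# else the last day of the series (the finite no-event penalty).
predict_from_state <- function(state, fstar, fd) {
  n <- length(fd)
  pred <- integer(n)
  reached <- logical(n)
  for (i in seq_len(n)) {
    cum <- state$cums[[i]]
    if (!is.na(fstar) && cum[length(cum)] >= fstar) {
      pred[i] <- state$t0 + which.max(cum >= fstar) - 1L
      reached[i] <- TRUE
    } else {
      pred[i] <- fd[[i]]$last
      reached[i] <- FALSE
    }
  }
  list(pred = pred, reached = reached)
}

# Loss with fstar profiled out: SSres of predicted vs observed event days.
profiled_eval <- function(model, theta, fd) {
  state <- forcing_state(model, theta, fd)
  fs <- fstar_from_state(state)
  pr <- predict_from_state(state, fs$fstar, fd)
  obs <- vapply(fd, function(e) e$obs_day, 1L)
  list(loss = sum((pr$pred - obs)^2), fstar = fs$fstar,
       pred = pr$pred, reached = pr$reached, excluded = fs$excluded)
}

eval_with_fstar <- function(model, theta, fstar, fd) {
  state <- forcing_state(model, theta, fd)
  predict_from_state(state, fstar, fd)
}

#' Sum-of-squares objective for a full parameter set
#'
#' Residual sum of squares (days squared) between observed event days and
#' the days predicted by `params` (including its `fstar`). Variety-years
#' whose event is never reached within the series are predicted at the last
#' day of their series, a large but finite penalty. Minimizing SSres
#' simultaneously maximizes model efficiency and minimizes RMSE, so the
#' annealer's criterion and the reported selection metrics agree.
#'
#' @param params A `pheno_params` object with `fstar` set.
#' @param data A [pheno_dataset()].
#' @param bbch Stage code (`"09"` or `"61"`).
#' @param varieties Optional subset of varieties.
#' @return SSres (single non-negative number).
#' @export
objective <- function(params, data, bbch, varieties = NULL) {
  stopifnot(inherits(params, "pheno_params"))
  if (is.na(params$fstar)) stop("objective requires params$fstar")
  fd <- build_fit_data(data, bbch, varieties)
  theta <- unlist(params[theta_names(params$model)])
  pr <- eval_with_fstar(params$model, theta, params$fstar, fd)
  obs <- vapply(fd, function(e) e$obs_day, 1L)
  sum((pr$pred - obs)^2)
}

#' Profile the critical forcing total out of a threshold set
#'
#' Given fixed start day and temperature thresholds, estimates `fstar` as
#' the mean over variety-years of the cumulative forcing accumulated at the
#' observed event day. Years where no forcing has accumulated by the
#' observed day are excluded with a warning; if every year is excluded the
#' estimate is undefined and an error is raised. When an interval of
#' `fstar` values reproduces every observed day exactly and the mean falls
#' outside that interval, the estimate snaps into it (to its upper end), so
#' that data generated without noise are refit exactly.
#'
#' @param params A `pheno_params` object; its `fstar` is ignored.
#' @inheritParams objective
#' @return The estimated `fstar` (single positive number).
#' @export
estimate_fstar <- function(params, data, bbch, varieties = NULL) {
  stopifnot(inherits(params, "pheno_params"))
  fd <- build_fit_data(data, bbch, varieties)
  theta <- unlist(params[theta_names(params$model)])
  state <- forcing_state(params$model, theta, fd)
  fs <- fstar_from_state(state)
  if (is.na(fs$fstar)) {
    stop("fstar undefined: no forcing accumulated by the observed day in any variety-year")
  }
  if (length(fs$excluded)) {
    lab <- vapply(fd[fs$excluded],
                  function(e) sprintf("%s %d", e$variety, e$year), "")
    warning("excluded variety-year(s) with zero forcing at the observed day: ",
            paste(lab, collapse = ", "))
  }
  fs$fstar
}

#' Profiled objective: loss, fstar and predictions for a threshold set
#'
#' Evaluates the fitting criterion exactly as the annealer does: `fstar` is
#' profiled out via the rule of [estimate_fstar()], and the loss is the
#' SSres of the resulting predictions. Useful for exhaustive-grid checks of
#' the annealer.
#'
#' @inheritParams estimate_fstar
#' @return A list: `loss` (SSres), `fstar`, `predictions` (data frame with
#'   `variety`, `year`, `observed`, `predicted`, `reached`).
#' @export
profiled_objective <- function(params, data, bbch, varieties = NULL) {
  stopifnot(inherits(params, "pheno_params"))
  fd <- build_fit_data(data, bbch, varieties)
  theta <- unlist(params[theta_names(params$model)])
  ev <- profiled_eval(params$model, theta, fd)
  list(loss = ev$loss, fstar = ev$fstar,
       predictions = prediction_frame(fd, ev$pred, ev$reached))
}

prediction_frame <- function(fd, pred, reached) {
  data.frame(
    variety = vapply(fd, function(e) e$variety, ""),
    year = vapply(fd, function(e) e$year, 1L),
    observed = vapply(fd, function(e) e$obs_day, 1L),
    predicted = pred,
    reached = reached
  )
}

# ---------------------------------------------------------------------------
# Metropolis simulated annealing.

reflect_bounds <- function(v, lo, hi) {
  if (lo == hi) return(lo)
  span <- hi - lo
  while (v < lo || v > hi) {
    if (v < lo) v <- lo + (lo - v)
    if (v > hi) v <- hi - (v - hi)
    # guard against pathological overshoot far outside the span
    if (abs(v - lo) > 3 * span) v <- lo + abs(v - lo) %% span
  }
  v
}

snap_grid <- function(v, lo, hi, step) {
  v <- lo + round((v - lo) / step) * step
  min(max(v, lo), hi)
}

theta_valid <- function(model, theta) {
  if (model == "triangular") {
    theta[["tmin_c"]] < theta[["topt"]] && theta[["topt"]] < theta[["tmax_c"]]
  } else if (model == "uniforc") {
    theta[["d"]] < 0 && theta[["e"]] > 0
  } else TRUE
}

random_theta <- function(space, model) {
  for (try in 1:500) {
    theta <- stats::setNames(numeric(nrow(space)), space$name)
    for (j in seq_len(nrow(space))) {
      if (space$step[j] > 0) {
        k <- floor((space$upper[j] - space$lower[j]) / space$step[j])
        theta[j] <- space$lower[j] + space$step[j] * sample(0:k, 1)
      } else {
        theta[j] <- stats::runif(1, space$lower[j], space$upper[j])
      }
    }
    if (theta_valid(model, theta)) return(theta)
  }
  stop("could not draw a valid starting point from the search space")
}

propose_theta <- function(theta, space, model, prop_sd) {
  j <- sample.int(nrow(space), 1)
  cand <- theta
  if (space$step[j] > 0) {
    move <- space$step[j] * sample.int(3, 1) * sample(c(-1, 1), 1)
    v <- reflect_bounds(theta[j] + move, space$lower[j], space$upper[j])
    cand[j] <- snap_grid(v, space$lower[j], space$upper[j], space$step[j])
  } else {
    v <- theta[j] + stats::rnorm(1, 0, prop_sd)
    cand[j] <- reflect_bounds(v, space$lower[j], space$upper[j])
  }
  cand
}

anneal_once <- function(model, space, fd, seed, schedule) {
  withr::with_seed(seed, {
    # draw a start where the event is reachable: states whose thresholds
    # let no year accumulate forcing form a flat plateau of the loss
    theta <- random_theta(space, model)
    cur <- profiled_eval(model, theta, fd)
    n_evals <- 1L
    tries <- 0L
    while (is.na(cur$fstar) && tries < 50L) {
      theta <- random_theta(space, model)
      cur <- profiled_eval(model, theta, fd)
      n_evals <- n_evals + 1L
      tries <- tries + 1L
    }
    best_theta <- theta
    best <- cur

    temp <- schedule$t_init
    if (is.null(temp)) {
      # calibrate so ~80% of initial uphill moves are accepted
      ups <- numeric(0)
      for (i in 1:30) {
        cand <- propose_theta(theta, space, model, schedule$prop_sd)
        if (!theta_valid(model, cand)) next
        l <- profiled_eval(model, cand, fd)$loss
        n_evals <- n_evals + 1L
        if (l > cur$loss) ups <- c(ups, l - cur$loss)
      }
      temp <- if (length(ups)) mean(ups) / log(1 / 0.8) else 1
    }
    t_floor <- temp * 1e-6

    stale <- 0L
    for (k in seq_len(schedule$max_temps)) {
      improved <- FALSE
      for (i in seq_len(schedule$iters_per_temp)) {
        cand <- propose_theta(theta, space, model, schedule$prop_sd)
        if (!theta_valid(model, cand)) next
        ev <- profiled_eval(model, cand, fd)
        n_evals <- n_evals + 1L
        dl <- ev$loss - cur$loss
        if (dl <= 0 || stats::runif(1) < exp(-dl / temp)) {
          theta <- cand
          cur <- ev
          if (cur$loss < best$loss) {
            best_theta <- theta
            best <- cur
            improved <- TRUE
          }
        }
        if (best$loss == 0) break
      }
      if (best$loss == 0) break
      stale <- if (improved) 0L else stale + 1L
      if (stale >= schedule$patience) break
      temp <- temp * schedule$cooling
      if (temp < t_floor) break
    }

    if (schedule$polish && best$loss > 0) {
      pol <- polish_theta(model, space, best_theta, best, fd,
                          schedule$prop_sd, schedule$polish_budget)
      best_theta <- pol$theta
      best <- pol$ev
      n_evals <- n_evals + pol$n_evals
    }

    list(theta = best_theta, loss = best$loss, fstar = best$fstar,
         n_evals = n_evals)
  })
}

# Deterministic coordinate descent around the annealer's best point.
polish_theta <- function(model, space, theta, ev, fd, prop_sd, budget) {
  n_evals <- 0L
  steps <- lapply(seq_len(nrow(space)), function(j) {
    if (space$step[j] > 0) space$step[j] * c(4, 2, 1)
    else prop_sd * c(4, 2, 1, 0.5, 0.2, 0.1, 0.04, 0.01)
  })
  max_len <- max(lengths(steps))
  for (lev in seq_len(max_len)) {
    repeat {
      improved <- FALSE
      for (j in seq_len(nrow(space))) {
        st <- steps[[j]]
        s <- st[min(lev, length(st))]
        for (sgn in c(-1, 1)) {
          if (n_evals >= budget) return(list(theta = theta, ev = ev, n_evals = n_evals))
          cand <- theta
          v <- reflect_bounds(theta[j] + sgn * s, space$lower[j], space$upper[j])
          cand[j] <- if (space$step[j] > 0) {
            snap_grid(v, space$lower[j], space$upper[j], space$step[j])
          } else v
          if (cand[j] == theta[j] || !theta_valid(model, cand)) next
          e2 <- profiled_eval(model, cand, fd)
          n_evals <- n_evals + 1L
          if (e2$loss < ev$loss) {
            theta <- cand
            ev <- e2
            improved <- TRUE
            if (ev$loss == 0) return(list(theta = theta, ev = ev, n_evals = n_evals))
          }
        }
      }
      if (!improved) break
    }
  }
  list(theta = theta, ev = ev, n_evals = n_evals)
}

derive_seed <- function(root, k) {
  as.integer((as.numeric(root) + 104729 * k) %% 2147483629L) + 1L
}

#' Fit a forcing model by multi-start Metropolis simulated annealing
#'
#' Minimizes the profiled SSres objective (see [profiled_objective()]) over
#' the threshold parameters of `space`, restarting from `starts`
#' independent seeded initial points. The reported per-parameter
#' (max; min) ranges span all starts whose final loss lies within 5% of the
#' best loss found. Ties between equal-loss starts are broken
#' deterministically (smallest base/optimum temperature, then earliest
#' `t0`, then remaining parameters).
#'
#' @param space A [param_space()].
#' @param data A [pheno_dataset()].
#' @param bbch Stage code (`"09"` or `"61"`).
#' @param varieties Optional subset of varieties to fit on.
#' @param seed Root seed; per-start seeds are derived from it.
#' @param starts Number of annealing restarts.
#' @param schedule A [sa_schedule()].
#' @param window_start Optional first day of the dataset window (1 for the
#'   January window); series are clipped to `day >= window_start`.
#' @return An object of class `fit_result`: fitted `params` (including the
#'   profiled `fstar`), `sum_heat` (= `fstar`), `ranges` (per-parameter
#'   max/min across near-best starts), `metrics` ([fit_metrics()] on the
#'   fitting data), `predictions`, `loss`, and bookkeeping fields.
#' @export
anneal <- function(space, data, bbch, varieties = NULL, seed = 1L,
                   starts = 10L, schedule = sa_schedule(),
                   window_start = NULL) {
  check_space(space)
  model <- attr(space, "model")
  fd <- build_fit_data(data, bbch, varieties, window_start)
  if (length(fd) < 2L) stop("annealing requires at least 2 variety-years")

  # clamp t0 to meteorology coverage, and below the earliest observed
  # event: accumulation starting after an observed event cannot predict it
  cov_lo <- max(vapply(fd, function(e) e$first, 1L))
  cov_hi <- min(c(vapply(fd, function(e) e$last, 1L),
                  vapply(fd, function(e) e$obs_day, 1L) - 1L))
  i_t0 <- match("t0", space$name)
  space$lower[i_t0] <- max(space$lower[i_t0], cov_lo)
  space$upper[i_t0] <- min(space$upper[i_t0], cov_hi)
  check_space(space)

  runs <- vector("list", starts)
  for (k in seq_len(starts)) {
    runs[[k]] <- anneal_once(model, space, fd, derive_seed(seed, k), schedule)
  }

  losses <- vapply(runs, function(r) r$loss, 1)
  thetas <- do.call(rbind, lapply(runs, function(r) r$theta))
  ord_cols <- list(losses)
  for (nm in intersect(c("tb", "topt", "e"), colnames(thetas))) {
    ord_cols <- c(ord_cols, list(thetas[, nm]))
  }
  ord_cols <- c(ord_cols, list(thetas[, "t0"]))
  for (nm in setdiff(colnames(thetas), c("tb", "topt", "e", "t0"))) {
    ord_cols <- c(ord_cols, list(thetas[, nm]))
  }
  best_i <- do.call(order, ord_cols)[1]
  best <- runs[[best_i]]

  band <- if (best$loss == 0) 1e-12 else best$loss * 1.05
  near <- which(losses <= band)
  vals <- cbind(thetas[near, , drop = FALSE],
                fstar = vapply(runs[near], function(r) r$fstar, 1))
  rng <- function(v) if (all(is.na(v))) c(NA_real_, NA_real_) else range(v, na.rm = TRUE)
  ranges <- data.frame(
    param = colnames(vals),
    max = apply(vals, 2, function(v) rng(v)[2]),
    min = apply(vals, 2, function(v) rng(v)[1]),
    row.names = NULL
  )

  params <- params_from_theta(model, best$theta, best$fstar)
  pr <- eval_with_fstar(model, best$theta, best$fstar, fd)
  predictions <- prediction_frame(fd, pr$pred, pr$reached)
  metrics <- fit_metrics(predictions$observed, predictions$predicted)

  structure(
    list(model = model, params = params, sum_heat = best$fstar,
         ranges = ranges, metrics = metrics, predictions = predictions,
         loss = best$loss, seed = seed, starts = starts,
         start_losses = losses,
         n_evals = sum(vapply(runs, function(r) r$n_evals, 1L)),
         window_start = window_start, bbch = format_bbch(bbch)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  vals <- x$params[setdiff(names(x$params), "model")]
  cat(sprintf(
    "<fit_result> %s, BBCH %s: %s\n  EFF = %.3f, RMSE = %.3f, MAD = %.3f (n = %d), SSres = %.3f\n",
    x$model, x$bbch,
    paste(sprintf("%s=%s", names(vals),
                  vapply(vals, function(v) format(v, digits = 6), "")),
          collapse = ", "),
    x$metrics$eff, x$metrics$rmse, x$metrics$mad, x$metrics$n, x$loss
  ))
  invisible(x)
}

#' Calibrate a model independently for each variety
#'
#' Runs [anneal()] on each variety's own observations. Varieties with fewer
#' than 2 years are skipped with a warning. Each variety's annealing uses
#' the same root seed, so identical data yield identical fits.
#'
#' @inheritParams anneal
#' @param model Model type to fit.
#' @return Named list of [anneal()] results, one per calibrated variety.
#' @export
calibrate_per_variety <- function(data, bbch, model = "gdd", seed = 1L,
                                  starts = 10L, schedule = sa_schedule(),
                                  window_start = NULL) {
  obs <- data$obs[data$obs$bbch == format_bbch(bbch), , drop = FALSE]
  varieties <- sort(unique(obs$variety))
  fits <- list()
  for (v in varieties) {
    if (sum(obs$variety == v) < 2L) {
      warning("skipping variety '", v, "': fewer than 2 years of observations")
      next
    }
    fits[[v]] <- anneal(param_space(model, window = if (is.null(window_start) || window_start < 1) "sep" else "jan"),
                        data, bbch, varieties = v, seed = seed,
                        starts = starts, schedule = schedule,
                        window_start = window_start)
  }
  fits
}

#' Validate a fitted model on another variety's data (frozen parameters)
#'
#' Applies a donor [anneal()] fit, with all parameters frozen, to a
#' recipient dataset and returns goodness-of-fit metrics. Validating a
#' donor on its own fitting data reproduces its estimation metrics exactly.
#'
#' @param fit A `fit_result` (the donor model).
#' @inheritParams anneal
#' @return A list: `metrics` ([fit_metrics()]) and `predictions`.
#' @export
external_validate <- function(fit, data, bbch = fit$bbch, varieties = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  fd <- build_fit_data(data, bbch, varieties, fit$window_start)
  theta <- unlist(fit$params[theta_names(fit$model)])
  pr <- eval_with_fstar(fit$model, theta, fit$params$fstar, fd)
  predictions <- prediction_frame(fd, pr$pred, pr$reached)
  list(metrics = fit_metrics(predictions$observed, predictions$predicted),
       predictions = predictions)
}

#' Cross-variety validation grid
#'
#' Builds the donor x recipient grid of efficiency and RMSE: each fitted
#' variety model (columns) is applied with frozen parameters to every
#' variety's dataset (rows). Diagonal cells are the donors' estimation
#' metrics.
#'
#' @param fits Named list of per-variety `fit_result`s
#'   (from [calibrate_per_variety()]).
#' @inheritParams anneal
#' @return An object of class `validation_matrix`: matrices `eff` and
#'   `rmse` (rows = recipient variety, columns = donor model) and a long
#'   data frame `table`.
#' @export
validation_matrix <- function(fits, data, bbch) {
  donors <- names(fits)
  obs <- data$obs[data$obs$bbch == format_bbch(bbch), , drop = FALSE]
  recipients <- sort(unique(obs$variety))
  eff <- matrix(NA_real_, length(recipients), length(donors),
                dimnames = list(recipients, donors))
  rmse_m <- eff
  rows <- list()
  for (d in donors) {
    for (r in recipients) {
      val <- external_validate(fits[[d]], data, bbch, varieties = r)
      eff[r, d] <- val$metrics$eff
      rmse_m[r, d] <- val$metrics$rmse
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d, recipient = r,
        phase = if (d == r) "estimation" else "validation",
        eff = val$metrics$eff, rmse = val$metrics$rmse,
        mad = val$metrics$mad, n = val$metrics$n
      )
    }
  }
  structure(list(eff = eff, rmse = rmse_m, table = do.call(rbind, rows),
                 bbch = format_bbch(bbch)),
            class = "validation_matrix")
}

#' @export
print.validation_matrix <- function(x, ...) {
  cat(sprintf("<validation_matrix> BBCH %s - EFF (rows: data, cols: model)\n",
              x$bbch))
  print(round(x$eff, 3))
  invisible(x)
}

#' Fit one pooled model across all varieties
#'
#' Calibrates a single parameter set on the pooled observations of every
#' variety (the "global" model), e.g. 12 years x 4 varieties = 48
#' observations per phenophase in the default synthetic design.
#'
#' @inheritParams calibrate_per_variety
#' @return A `fit_result` on the pooled data.
#' @export
fit_global <- function(data, bbch, model = "gdd", seed = 1L, starts = 10L,
                       schedule = sa_schedule(), window_start = NULL) {
  anneal(param_space(model, window = if (is.null(window_start) || window_start < 1) "sep" else "jan"),
         data, bbch, varieties = NULL, seed = seed, starts = starts,
         schedule = schedule, window_start = window_start)
}

#' Compare dataset windows for the start of forcing accumulation
#'
#' Fits the same model under two dataset windows: one opening on
#' 1 September of the previous year (start day may be negative) and one
#' opening on 1 January of the event year. Reports both fits and selects
#' the window with the higher efficiency; ties go to the January window,
#' the simpler choice.
#'
#' @inheritParams calibrate_per_variety
#' @param varieties Optional subset of varieties.
#' @return A list of class `window_comparison`: fits `sep` and `jan`, a
#'   summary data frame `table`, and `selected` (`"jan"` or `"sep"`).
#' @export
compare_start_windows <- function(data, bbch, model = "gdd",
                                  varieties = NULL, seed = 1L, starts = 3L,
                                  schedule = sa_schedule()) {
  fit_sep <- anneal(param_space(model, window = "sep"), data, bbch,
                    varieties, seed = seed, starts = starts,
                    schedule = schedule, window_start = NULL)
  fit_jan <- anneal(param_space(model, window = "jan"), data, bbch,
                    varieties, seed = seed, starts = starts,
                    schedule = schedule, window_start = 1L)
  selected <- if (fit_jan$metrics$eff >= fit_sep$metrics$eff) "jan" else "sep"
  tab <- data.frame(
    window = c("sep", "jan"),
    eff = c(fit_sep$metrics$eff, fit_jan$metrics$eff),
    rmse = c(fit_sep$metrics$rmse, fit_jan$metrics$rmse)
  )
  structure(list(sep = fit_sep, jan = fit_jan, table = tab,
                 selected = selected),
            class = "window_comparison")
}

#' @export
print.window_comparison <- function(x, ...) {
  cat(sprintf("<window_comparison> selected: %s\n", x$selected))
  print(x$table)
  invisible(x)
}

#' Select among fitted model types, preferring simplicity
#'
#' Given fits of different model types to the same data, returns the name
#' of the simplest model whose efficiency is within `tol` of the best.
#' Complexity order: GDD (3 parameters) < UniFORC (4) < triangular (5).
#'
#' @param fits Named list of `fit_result`s, names in
#'   `c("gdd", "triangular", "uniforc")`.
#' @param tol Efficiency difference treated as "equal capability".
#' @return The selected model name.
#' @export
select_model <- function(fits, tol = 0.01) {
  complexity <- c(gdd = 3, uniforc = 4, triangular = 5)
  effs <- vapply(fits, function(f) f$metrics$eff, 1)
  ok <- names(effs)[effs >= max(effs) - tol]
  ok[order(complexity[ok], -effs[ok])][1]
}
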