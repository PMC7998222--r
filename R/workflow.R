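#' Multistep calibration / validation / global-model workflow
#'
#' Runs the full modeling procedure on one phenophase of a dataset:
#'
#' 1. *Dataset window comparison* (optional): for each variety, the model
#'    is fitted with the dataset opening on 1 September of the previous
#'    year and again opening on 1 January of the event year; the window
#'    with the higher mean efficiency across varieties is retained (ties
#'    go to January).
#' 2. *Per-variety calibration*: each requested model type is calibrated
#'    independently on every variety ([calibrate_per_variety()]); when
#'    several model types are requested, one is selected by efficiency
#'    with a simplicity preference ([select_model()]).
#' 3. *Cross-variety external validation*: the selected model type's
#'    per-variety fits are applied with frozen parameters to every other
#'    variety ([validation_matrix()]); the donor whose model attains the
#'    highest mean efficiency on the *other* varieties is flagged as the
#'    recommended transfer model.
#' 4. *Global model*: a single parameter set is fitted on the pooled
#'    observations of all varieties ([fit_global()]).
#'
#' Alongside the fits, the result carries report tables: a per-variety
#' estimation table, the validation grid, difference-class frequencies and
#' regression-through-origin summaries for the donor and global models.
#'
#' @inheritParams anneal
#' @param models Character vector of model types to calibrate.
#' @param compare_windows Run step 1 (default `TRUE`).
#' @param window_starts Annealing restarts used in step 1 (a coarser
#'   search is enough to pick a window).
#' @return An object of class `multistep_result`.
#' @export
run_multistep <- function(data, bbch, models = "gdd", seed = 1L,
                          starts = 10L, schedule = sa_schedule(),
                          compare_windows = TRUE, window_starts = 3L) {
  stopifnot(inherits(data, "pheno_dataset"))
  bbch <- format_bbch(bbch)

  windows <- NULL
  window_start <- 1L
  if (compare_windows) {
    obs <- data$obs[data$obs$bbch == bbch, , drop = FALSE]
    varieties <- sort(unique(obs$variety))
    windows <- lapply(varieties, function(v) {
      compare_start_windows(data, bbch, model = models[1], varieties = v,
                            seed = seed, starts = window_starts,
                            schedule = schedule)
    })
    names(windows) <- varieties
    eff_jan <- mean(vapply(windows, function(w) w$jan$metrics$eff, 1))
    eff_sep <- mean(vapply(windows, function(w) w$sep$metrics$eff, 1))
    window_start <- if (eff_jan >= eff_sep) 1L else NULL
  }

  fits_by_model <- lapply(models, function(m) {
    calibrate_per_variety(data, bbch, model = m, seed = seed,
                          starts = starts, schedule = schedule,
                          window_start = window_start)
  })
  names(fits_by_model) <- models

  selected_model <- if (length(models) == 1L) models else {
    mean_eff <- vapply(fits_by_model, function(fits) {
      mean(vapply(fits, function(f) f$metrics$eff, 1))
    }, 1)
    pseudo <- lapply(mean_eff, function(e) list(metrics = list(eff = e)))
    select_model(pseudo)
  }
  fits <- fits_by_model[[selected_model]]

  vm <- validation_matrix(fits, data, bbch)
  off_diag_eff <- vapply(colnames(vm$eff), function(d) {
    mean(vm$eff[setdiff(rownames(vm$eff), d), d])
  }, 1)
  off_diag_rmse <- vapply(colnames(vm$rmse), function(d) {
    mean(vm$rmse[setdiff(rownames(vm$rmse), d), d])
  }, 1)
  ord <- order(-off_diag_eff, off_diag_rmse, colnames(vm$eff))
  donor <- colnames(vm$eff)[ord[1]]

  global <- fit_global(data, bbch, model = selected_model, seed = seed,
                       starts = starts, schedule = schedule,
                       window_start = window_start)

  donor_val <- external_validate(
    fits[[donor]], data, bbch,
    varieties = setdiff(rownames(vm$eff), donor)
  )
  est_pred <- fits[[donor]]$predictions

  structure(
    list(
      bbch = bbch,
      models = models,
      selected_model = selected_model,
      window_start = window_start,
      windows = windows,
      fits_by_model = fits_by_model,
      fits = fits,
      estimation_table = metrics_table(fits),
      validation = vm,
      donor = donor,
      donor_validation = donor_val,
      donor_diff_classes = list(
        estimation = difference_classes(est_pred$observed, est_pred$predicted),
        validation = difference_classes(donor_val$predictions$observed,
                                        donor_val$predictions$predicted)
      ),
      donor_regression = list(
        estimation = origin_regression(est_pred$observed, est_pred$predicted),
        validation = origin_regression(donor_val$predictions$observed,
                                       donor_val$predictions$predicted)
      ),
      global = global,
      global_diff_classes = difference_classes(global$predictions$observed,
                                               global$predictions$predicted),
      global_regression = origin_regression(global$predictions$observed,
                                            global$predictions$predicted),
      seed = seed
    ),
    class = "multistep_result"
  )
}

#' @export
print.multistep_result <- function(x, ...) {
  cat(sprintf("<multistep_result> BBCH %s, model %s, window: %s\n",
              x$bbch, x$selected_model,
              if (is.null(x$window_start)) "1 Sep (previous year)" else "1 Jan"))
  cat("\nPer-variety estimation:\n")
  tab <- x$estimation_table
  print(tab[, setdiff(names(tab), c("bbch", "phase"))], row.names = FALSE,
        digits = 4)
  cat(sprintf("\nDonor for transfer: %s\n", x$donor))
  cat("\nValidation EFF grid (rows: data, cols: model):\n")
  print(round(x$validation$eff, 3))
  g <- x$global
  cat(sprintf(
    "\nGlobal model (n = %d): t0 = %d, EFF = %.3f, RMSE = %.3f\n",
    g$metrics$n, g$params$t0, g$metrics$eff, g$metrics$rmse
  ))
  invisible(x)
}
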