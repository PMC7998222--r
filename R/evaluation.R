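#' Goodness-of-fit metrics for predicted event dates
#'
#' Metrics used to select and validate phenology models, all computed on
#' paired vectors of observed and predicted event days (in days):
#'
#' * `efficiency()` — model efficiency
#'   `EFF = (SStot - SSres) / SStot = 1 - SSres / SStot`
#'   (Nash-Sutcliffe form): 1 for a perfect model, 0 for a model no better
#'   than the observed mean, unbounded below for worse models. Requires at
#'   least two observations with non-zero variance.
#' * `rmse()` — root mean square error `sqrt(SSres / n)`.
#' * `mean_abs_dev()` — mean absolute deviation `sum(|obs - pred|) / n`.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A single number.
#' @examples
#' obs <- c(100, 110, 120); pred <- c(101, 109, 121)
#' efficiency(obs, pred)   # 0.985
#' rmse(obs, pred)         # 1
#' mean_abs_dev(obs, pred) # 1
#' @export
efficiency <- function(observed, predicted) {
  check_pairs(observed, predicted)
  if (length(observed) < 2L) {
    stop("efficiency requires at least two observations")
  }
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) {
    stop("efficiency undefined: observed values have zero variance")
  }
  ssres <- sum((observed - predicted)^2)
  (sstot - ssres) / sstot
}

#' @rdname efficiency
#' @export
rmse <- function(observed, predicted) {
  check_pairs(observed, predicted)
  sqrt(sum((observed - predicted)^2) / length(observed))
}

#' @rdname efficiency
#' @export
mean_abs_dev <- function(observed, predicted) {
  check_pairs(observed, predicted)
  sum(abs(observed - predicted)) / length(observed)
}

check_pairs <- function(observed, predicted) {
  if (length(observed) == 0L) stop("empty input")
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (anyNA(observed) || anyNA(predicted)) stop("missing values in input")
  invisible(TRUE)
}

#' All three fit metrics at once
#'
#' @inheritParams efficiency
#' @return A list of class `fit_metrics`: `eff`, `rmse`, `mad`, `n`.
#' @export
fit_metrics <- function(observed, predicted) {
  structure(
    list(eff = efficiency(observed, predicted),
         rmse = rmse(observed, predicted),
         mad = mean_abs_dev(observed, predicted),
         n = length(observed)),
    class = "fit_metrics"
  )
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("<fit_metrics> EFF = %.3f, RMSE = %.3f, MAD = %.3f (n = %d)\n",
              x$eff, x$rmse, x$mad, x$n))
  invisible(x)
}

#' Linear regression through the origin of predicted on observed dates
#'
#' Fits `predicted = b0 * observed` with no intercept. A slope close to 1
#' indicates absence of systematic bias between predicted and observed
#' dates. The 95% confidence interval uses the zero-intercept model's
#' residual variance on n - 1 degrees of freedom.
#'
#' @inheritParams efficiency
#' @return A list of class `origin_regression`: `b0`, `ci95` (length-2
#'   vector), `se`, `n`.
#' @examples
#' origin_regression(c(100, 110), c(101, 109))$b0 # ~0.99955
#' @export
origin_regression <- function(observed, predicted) {
  check_pairs(observed, predicted)
  n <- length(observed)
  if (n < 2L) stop("origin regression requires at least two pairs")
  sxx <- sum(observed^2)
  if (sxx == 0) stop("origin regression undefined: all observed values zero")
  b0 <- sum(predicted * observed) / sxx
  resid <- predicted - b0 * observed
  s2 <- sum(resid^2) / (n - 1)
  se <- sqrt(s2 / sxx)
  tq <- stats::qt(0.975, df = n - 1)
  structure(
    list(b0 = b0, ci95 = c(b0 - tq * se, b0 + tq * se), se = se, n = n),
    class = "origin_regression"
  )
}

#' @export
print.origin_regression <- function(x, ...) {
  cat(sprintf("<origin_regression> b0 = %.4f (95%% CI %.4f .. %.4f, n = %d)\n",
              x$b0, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Frequency of absolute prediction errors by difference class
#'
#' Bins the absolute differences `|predicted - observed|` (days) into the
#' three classes \[0, 3\], (3, 6\] and (6, Inf) and reports the percentage
#' of cases in each. Boundary values fall in the lower class (3 days counts
#' as \[0, 3\], 6 days as (3, 6\]).
#'
#' @inheritParams efficiency
#' @return A data frame of class `difference_classes` with columns `class`,
#'   `n` and `pct` (percentages summing to 100).
#' @examples
#' difference_classes(c(100, 100, 100, 100), c(101, 102, 104, 107))
#' @export
difference_classes <- function(observed, predicted) {
  check_pairs(observed, predicted)
  d <- abs(predicted - observed)
  counts <- c(sum(d <= 3), sum(d > 3 & d <= 6), sum(d > 6))
  out <- data.frame(
    class = c("[0,3]", "(3,6]", "(6,Inf)"),
    n = counts,
    pct = 100 * counts / length(d)
  )
  class(out) <- c("difference_classes", "data.frame")
  out
}
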