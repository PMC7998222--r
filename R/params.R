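#' Model parameter sets
#'
#' Constructors for the parameter vectors of the three daily forcing models.
#' All three share a start day `t0` (on the back-extended day axis, see
#' [temperature_series()]) and a critical forcing total `fstar` (> 0,
#' degree-days for the GDD model, dimensionless forcing units for the
#' triangular and UniFORC models). `fstar` may be left `NA` while thresholds
#' are being calibrated; prediction requires a finite positive value.
#'
#' * `gdd_params()`: growing degree-days above a base temperature `tb`.
#' * `triangular_params()`: triangular response over cardinal temperatures
#'   `tmin_c < topt < tmax_c`, rate in \[0, 1\] peaking at `topt`.
#' * `uniforc_params()`: sigmoid response `1 / (1 + exp(d * (x - e)))` for
#'   temperatures >= 0 degC, with sharpness `d < 0` and mid-response
#'   temperature `e > 0`.
#'
#' @param t0 Integer start day of forcing accumulation.
#' @param tb Base temperature (degC), GDD model.
#' @param tmin_c,topt,tmax_c Cardinal temperatures (degC), triangular model.
#' @param d Sharpness of the sigmoid (dimensionless, < 0), UniFORC model.
#' @param e Mid-response temperature (degC, > 0), UniFORC model.
#' @param fstar Critical forcing total (> 0), or `NA` if not yet fixed.
#' @return An object of class `pheno_params` with subclass
#'   `gdd_params`, `triangular_params` or `uniforc_params`.
#' @examples
#' gdd_params(t0 = 49, tb = 5, fstar = 228.5)
#' uniforc_params(t0 = 70, d = -0.9, e = 11, fstar = 11.4)
#' @export
gdd_params <- function(t0, tb, fstar = NA_real_) {
  check_fstar(fstar)
  structure(
    list(model = "gdd", t0 = as.integer(t0), tb = as.numeric(tb),
         fstar = as.numeric(fstar)),
    class = c("gdd_params", "pheno_params")
  )
}

#' @rdname gdd_params
#' @export
triangular_params <- function(t0, tmin_c, topt, tmax_c, fstar = NA_real_) {
  if (!(tmin_c < topt && topt < tmax_c)) {
    stop("cardinal temperatures must satisfy tmin_c < topt < tmax_c")
  }
  check_fstar(fstar)
  structure(
    list(model = "triangular", t0 = as.integer(t0),
         tmin_c = as.numeric(tmin_c), topt = as.numeric(topt),
         tmax_c = as.numeric(tmax_c), fstar = as.numeric(fstar)),
    class = c("triangular_params", "pheno_params")
  )
}

#' @rdname gdd_params
#' @export
uniforc_params <- function(t0, d, e, fstar = NA_real_) {
  if (!(d < 0)) stop("UniFORC sharpness d must be negative")
  if (!(e > 0)) stop("UniFORC mid-response temperature e must be positive")
  check_fstar(fstar)
  structure(
    list(model = "uniforc", t0 = as.integer(t0), d = as.numeric(d),
         e = as.numeric(e), fstar = as.numeric(fstar)),
    class = c("uniforc_params", "pheno_params")
  )
}

check_fstar <- function(fstar) {
  if (!is.na(fstar) && !(fstar > 0)) stop("fstar must be > 0 (or NA)")
  invisible(TRUE)
}

#' @export
print.pheno_params <- function(x, ...) {
  vals <- x[setdiff(names(x), "model")]
  cat(sprintf(
    "<%s params> %s\n", x$model,
    paste(sprintf("%s=%s", names(vals), vapply(vals, format, "")), collapse = ", ")
  ))
  invisible(x)
}

# Daily forcing rates for a mean-temperature vector under a parameter set.
# Dispatch kept internal: the exported rate functions take scalar thresholds.
rate_for <- function(params, x) {
  switch(params$model,
    gdd = rf_gdd(x, params$tb),
    triangular = rf_triangular(x, params$tmin_c, params$topt, params$tmax_c),
    uniforc = rf_uniforc(x, params$d, params$e),
    stop("unknown model type: ", params$model)
  )
}

# Rebuild a pheno_params object from a model type and a named numeric vector
# of free parameters (as used by the annealer), plus an fstar.
params_from_theta <- function(model, theta, fstar = NA_real_) {
  switch(model,
    gdd = gdd_params(theta[["t0"]], theta[["tb"]], fstar),
    triangular = triangular_params(theta[["t0"]], theta[["tmin_c"]],
                                   theta[["topt"]], theta[["tmax_c"]], fstar),
    uniforc = uniforc_params(theta[["t0"]], theta[["d"]], theta[["e"]], fstar),
    stop("unknown model type: ", model)
  )
}

theta_names <- function(model) {
  switch(model,
    gdd = c("t0", "tb"),
    triangular = c("t0", "tmin_c", "topt", "tmax_c"),
    uniforc = c("t0", "d", "e"),
    stop("unknown model type: ", model)
  )
}
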