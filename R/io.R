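#' Read daily meteorology from CSV
#'
#' Expects columns `date` (ISO 8601), `tmin`, `tmean`, `tmax` (degC), one
#' row per day with no gaps. The file is split into one
#' [temperature_series()] per event year: every year whose 1 January -
#' 31 August span is fully covered yields a series, starting at
#' 1 September of the previous year when the file reaches back that far.
#'
#' @param path Path to the CSV file.
#' @return Named list of [temperature_series()] keyed by event year.
#' @export
read_meteorology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmean", "tmax")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("meteorology file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dates <- suppressWarnings(as.Date(df$date))
  if (anyNA(dates)) {
    i <- which(is.na(dates))[1]
    stop(sprintf("unparseable date '%s' on line %d", df$date[i], i + 1L))
  }
  ord <- order(dates)
  df <- df[ord, ]
  dates <- dates[ord]
  for (col in c("tmin", "tmean", "tmax")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]])) stop("non-numeric value in column ", col)
  }
  if (anyDuplicated(dates)) {
    stop("duplicate date in meteorology: ", dates[duplicated(dates)][1])
  }
  gaps <- which(diff(as.integer(dates)) > 1L)
  if (length(gaps)) {
    stop("missing day(s) in meteorology, first gap after ", dates[gaps[1]])
  }
  bad <- which(df$tmin > df$tmean | df$tmean > df$tmax)
  if (length(bad)) {
    stop(sprintf("tmin <= tmean <= tmax violated on line %d (%s)",
                 bad[1] + 1L, dates[bad[1]]))
  }

  years <- sort(unique(as.integer(format(dates, "%Y"))))
  out <- list()
  for (y in years) {
    jan1 <- as.Date(sprintf("%d-01-01", y))
    aug31 <- as.Date(sprintf("%d-08-31", y))
    if (min(dates) > jan1 || max(dates) < aug31) next
    from <- max(min(dates), as.Date(sprintf("%d-09-01", y - 1L)))
    keep <- dates >= from & dates <= aug31
    out[[as.character(y)]] <- temperature_series(
      day_index(dates[keep], y),
      df$tmin[keep], df$tmean[keep], df$tmax[keep], year = y
    )
  }
  if (!length(out)) stop("no event year with complete Jan-Aug coverage")
  out
}

#' Write daily meteorology to CSV
#'
#' Inverse of [read_meteorology()]: concatenates the per-year series back
#' into one `date, tmin, tmean, tmax` table (duplicated dates across
#' overlapping windows must agree and are written once).
#'
#' @param met Named list of [temperature_series()] keyed by event year.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meteorology <- function(met, path) {
  rows <- lapply(names(met), function(y) {
    s <- met[[y]]
    origin <- as.Date(sprintf("%s-01-01", y))
    data.frame(date = origin + (s$day - 1L), tmin = s$tmin,
               tmean = s$tmean, tmax = s$tmax)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$date), ]
  dup <- duplicated(df$date)
  if (any(dup)) {
    both <- df[df$date %in% df$date[dup], ]
    agg <- stats::aggregate(cbind(tmin, tmean, tmax) ~ date, both,
                            function(v) diff(range(v)))
    if (any(as.matrix(agg[-1]) > 1e-9)) {
      stop("conflicting temperatures for duplicated date ",
           agg$date[which(rowSums(as.matrix(agg[-1]) > 1e-9) > 0)[1]])
    }
    df <- df[!dup, ]
  }
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read phenological observations from CSV
#'
#' Expects columns `variety`, `year`, `bbch`, `doy`. Stage codes must be
#' `09` (budburst) or `61` (flowering); `doy` must lie in 1..200; one event
#' per (variety, year, bbch).
#'
#' @param path Path to the CSV file.
#' @return Data frame of validated observations.
#' @export
read_phenology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bbch = "character"))
  need <- c("variety", "year", "bbch", "doy")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("phenology file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$bbch <- format_bbch(df$bbch)
  bad <- setdiff(unique(df$bbch), c("09", "61"))
  if (length(bad)) {
    stop("unknown BBCH stage code(s): ", paste(bad, collapse = ", "))
  }
  df$doy <- as.integer(df$doy)
  if (anyNA(df$doy) || any(df$doy < 1L | df$doy > 200L)) {
    stop("doy must be an integer in 1..200")
  }
  if (anyDuplicated(df[c("variety", "year", "bbch")])) {
    stop("duplicate (variety, year, bbch) rows: one event per variety-year-stage")
  }
  df[need]
}

#' Write phenological observations to CSV
#'
#' @param obs Data frame with columns `variety`, `year`, `bbch`, `doy`
#'   (e.g. the `obs` element of a [pheno_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenology <- function(obs, path) {
  obs <- as.data.frame(obs)[c("variety", "year", "bbch", "doy")]
  obs$bbch <- format_bbch(obs$bbch)
  utils::write.csv(obs, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a pheno_dataset from a meteorology and a phenology CSV
#'
#' @param met_path,pheno_path File paths.
#' @return A [pheno_dataset()].
#' @export
read_dataset <- function(met_path, pheno_path) {
  pheno_dataset(read_meteorology(met_path), read_phenology(pheno_path))
}

# Flat metrics table for per-variety fits (one row per variety).
metrics_table <- function(fits, phase = "estimation") {
  do.call(rbind, lapply(names(fits), function(v) {
    f <- fits[[v]]
    pars <- f$params[setdiff(names(f$params), c("model", "fstar"))]
    data.frame(
      variety = v, bbch = f$bbch, model = f$model, phase = phase,
      t(unlist(pars)), fstar = f$params$fstar,
      eff = f$metrics$eff, rmse = f$metrics$rmse, mad = f$metrics$mad,
      n = f$metrics$n, ssres = f$loss
    )
  }))
}

# Serializable summary of a fit (params + ranges + metrics), used by the
# CLI to pass fitted models between commands.
fit_to_list <- function(fit) {
  list(
    model = fit$model, bbch = fit$bbch,
    params = fit$params[setdiff(names(fit$params), "model")],
    ranges = fit$ranges,
    window_start = fit$window_start,
    metrics = unclass(fit$metrics),
    loss = fit$loss, seed = fit$seed, starts = fit$starts
  )
}

fit_from_list <- function(x) {
  theta <- stats::setNames(as.numeric(x$params[theta_names(x$model)]),
                           theta_names(x$model))
  structure(
    list(model = x$model, bbch = format_bbch(x$bbch),
         params = params_from_theta(x$model, theta, as.numeric(x$params$fstar)),
         window_start = if (is.null(x$window_start)) NULL else as.integer(x$window_start),
         metrics = structure(x$metrics, class = "fit_metrics"),
         loss = x$loss, seed = x$seed, starts = x$starts),
    class = "fit_result"
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", null = "null",
                       na = "null")
  invisible(path)
}
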