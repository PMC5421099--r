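## File formats
##
## PPG recordings travel as two-column CSV (time_s, amplitude) with a
## `# fs=<Hz>` comment header; fiducial ground truth as a JSON sidecar;
## populations, feature tables and BP series as plain CSV; fitted models
## as JSON carrying the intercept, coefficients and training feature
## statistics.

#' Write / read a PPG recording as CSV
#'
#' @param signal a `ppg_signal`.
#' @param path file path.
#' @returns `write_ppg_csv` returns `path` invisibly; `read_ppg_csv`
#'   returns a `ppg_signal`.
#' @export
write_ppg_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ppg_signal"))
  writeLines(sprintf("# fs=%g", signal_fs(signal)), path)
  readr::write_csv(tibble::tibble(time_s = signal$time,
                                  amplitude = signal$amplitude),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_ppg_csv
#' @param fs sampling-rate override in Hz, used when the file has no
#'   `# fs=` header.
#' @export
read_ppg_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^# fs=([0-9.]+)", first))[[1L]]
  if (length(m) == 2L) {
    fs <- as.numeric(m[2L])
  } else if (is.null(fs)) {
    ppgbp_abort("no `# fs=` header and no `fs` override supplied",
                "ppgbp_error_input")
  }
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  ppg_signal(d$amplitude, fs = fs)
}

#' Write / read fiducial ground truth as JSON
#'
#' @param truth ground-truth tibble from [synthesize_ppg()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read a feature table as CSV
#'
#' One row per measurement window; columns are the 20 feature names plus
#' any identifier/target columns present.
#'
#' @param features feature tibble.
#' @param path file path.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a fitted model as JSON
#'
#' The serialisation carries the target, intercept, named coefficients
#' and the training-set feature means/SDs for diagnostics.
#'
#' @param model a `bp_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "bp_model"))
  obj <- list(target = model$target,
              intercept = model$intercept,
              features = as.list(model$coefficients),
              n = model$n, sigma = model$sigma, method = model$method,
              feature_stats = model$feature_stats)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(obj$features)
  if (is.null(coefs)) coefs <- setNames(numeric(0), character(0))
  fit <- list(sigma2 = obj$sigma^2, rss = NA_real_, se = NA_real_,
              t = NA_real_, p = NA_real_, df = NA_integer_)
  new_bp_model(obj$intercept, coefs, obj$target, fit, obj$n,
               tibble::as_tibble(obj$feature_stats), method = obj$method)
}

#' Write / read a blood-pressure series as CSV
#'
#' Columns: `time` (ISO-8601), `sbp`, `dbp`.
#'
#' @param data BP series tibble.
#' @param path file path.
#' @export
write_bp_series_csv <- function(data, path) {
  check_bp_series(data)
  out <- data
  out$time <- format(data$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_bp_series_csv
#' @export
read_bp_series_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(time = readr::col_character()))
  d$time <- as.POSIXct(d$time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  check_bp_series(d)
  d
}

#' Write / read a population table as CSV
#'
#' @param population tibble from [generate_population()].
#' @param path file path.
#' @export
write_population_csv <- function(population, path) {
  readr::write_csv(population, path)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write an evaluation report as JSON
#'
#' @param eval a `bp_eval`.
#' @param path file path.
#' @export
write_eval_json <- function(eval, path) {
  stopifnot(inherits(eval, "bp_eval"))
  obj <- list(r = eval$r, mean_error = eval$mean_error,
              sd_error = eval$sd_error, n = eval$n, method = eval$method)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
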