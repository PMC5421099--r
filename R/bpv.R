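## 24-hour blood-pressure variability analytics
##
## Clock conventions: daytime is the half-open local-clock window
## [06:00, 22:00), nighttime is [22:00, 06:00); a reading stamped exactly
## 22:00 is nighttime. Dipping is judged on the percentage decline of the
## nocturnal SBP mean relative to the daytime SBP mean; the DBP decline
## is computed and reported but does not drive the label.

is_daytime <- function(time, day_start = 6L, night_start = 22L) {
  hr <- as.integer(format(time, "%H"))
  hr >= day_start & hr < night_start
}

check_bp_series <- function(data) {
  need <- c("time", "sbp", "dbp")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    ppgbp_abort(paste0("BP series must have columns time, sbp, dbp; missing: ",
                       paste(miss, collapse = ", ")), "ppgbp_error_input")
  }
  invisible(data)
}

#' Daytime and nighttime mean blood pressures
#'
#' Arithmetic means of SBP and DBP over the daytime window
#' \code{[06:00, 22:00)} and the nighttime window \code{[22:00, 06:00)}
#' of local clock time.
#'
#' @param data BP series: tibble with `time` (POSIXct), `sbp`, `dbp`.
#' @returns one-row tibble with `day_mean_sbp`, `day_mean_dbp`,
#'   `night_mean_sbp`, `night_mean_dbp` and the reading counts
#'   `n_day`, `n_night`.
#' @export
day_night_means <- function(data) {
  check_bp_series(data)
  day <- is_daytime(data$time)
  if (!any(day)) {
    ppgbp_abort("no readings in the daytime window [06:00, 22:00)",
                "ppgbp_error_coverage")
  }
  if (all(day)) {
    ppgbp_abort("no readings in the nighttime window [22:00, 06:00)",
                "ppgbp_error_coverage")
  }
  tibble::tibble(day_mean_sbp = mean(data$sbp[day]),
                 day_mean_dbp = mean(data$dbp[day]),
                 night_mean_sbp = mean(data$sbp[!day]),
                 night_mean_dbp = mean(data$dbp[!day]),
                 n_day = sum(day), n_night = sum(!day))
}

#' Classify the nocturnal dipping pattern
#'
#' The percentage decline is `100 * (day - night) / day` on the SBP
#' means. Patterns partition the decline axis: negative declines are
#' `riser`, \code{[0, 10)} `nondipper`, \code{[10, 20)} `dipper` and 20%
#' or more `extreme-dipper` (the boundary values 10 and 20 go to the
#' stronger-dipping class, the standard clinical convention).
#'
#' @param day_mean_sbp,night_mean_sbp daytime and nighttime SBP means,
#'   mmHg (vectorised).
#' @param day_mean_dbp,night_mean_dbp optional DBP means; their decline
#'   is reported but does not affect the label.
#' @returns tibble with the means, `decline_pct`, `decline_pct_dbp` and
#'   `pattern` (factor with levels riser, nondipper, dipper,
#'   extreme-dipper).
#' @export
#' @examples
#' classify_dipping(120, 105)$pattern  # dipper (12.5% decline)
classify_dipping <- function(day_mean_sbp, night_mean_sbp,
                             day_mean_dbp = NA_real_,
                             night_mean_dbp = NA_real_) {
  if (any(day_mean_sbp <= 0)) {
    ppgbp_abort("daytime mean SBP must be positive", "ppgbp_error_input")
  }
  decline <- 100 * (day_mean_sbp - night_mean_sbp) / day_mean_sbp
  decline_dbp <- 100 * (day_mean_dbp - night_mean_dbp) / day_mean_dbp
  pattern <- cut(decline, breaks = c(-Inf, 0, 10, 20, Inf),
                 labels = DIPPING_PATTERNS, right = FALSE)
  tibble::tibble(day_mean_sbp = day_mean_sbp,
                 night_mean_sbp = night_mean_sbp,
                 decline_pct = decline,
                 decline_pct_dbp = decline_dbp,
                 pattern = pattern)
}

#' Dipping pattern of a 24-hour BP series
#'
#' Convenience wrapper: [day_night_means()] followed by
#' [classify_dipping()].
#'
#' @param data BP series tibble (`time`, `sbp`, `dbp`).
#' @returns one-row classification tibble, see [classify_dipping()].
#' @export
dipping_pattern <- function(data) {
  m <- day_night_means(data)
  classify_dipping(m$day_mean_sbp, m$night_mean_sbp,
                   m$day_mean_dbp, m$night_mean_dbp)
}

#' Daily blood-pressure statistics
#'
#' The per-day summary shown to application users: mean SBP, mean DBP,
#' maximum SBP and minimum DBP for a calendar day.
#'
#' @param data BP series tibble.
#' @param date the calendar day (`Date` or coercible).
#' @returns one-row tibble `date`, `mean_sbp`, `mean_dbp`, `max_sbp`,
#'   `min_dbp`, `n`.
#' @export
daily_stats <- function(data, date) {
  check_bp_series(data)
  date <- as.Date(date)
  sel <- as.Date(data$time) == date
  if (!any(sel)) {
    ppgbp_abort(sprintf("no readings on %s", format(date)),
                "ppgbp_error_coverage")
  }
  tibble::tibble(date = date,
                 mean_sbp = mean(data$sbp[sel]),
                 mean_dbp = mean(data$dbp[sel]),
                 max_sbp = max(data$sbp[sel]),
                 min_dbp = min(data$dbp[sel]),
                 n = sum(sel))
}

#' Histogram of blood-pressure readings
#'
#' Half-open bins `[lo, lo + w)`: a reading exactly on a bin edge falls
#' in the bin whose lower edge it matches. Counts over all bins equal the
#' number of readings inside `range`.
#'
#' @param data BP series tibble.
#' @param bin_width bin width, mmHg (> 0).
#' @param range numeric `c(lo, hi)`; default spans the data, snapped to
#'   bin-width multiples.
#' @param which `"sbp"` or `"dbp"`.
#' @returns tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
bp_histogram <- function(data, bin_width = 10, range = NULL, which = "sbp") {
  check_bp_series(data)
  if (bin_width <= 0) {
    ppgbp_abort("`bin_width` must be positive", "ppgbp_error_input")
  }
  x <- data[[which]]
  if (is.null(range)) {
    if (!length(x)) {
      range <- c(0, bin_width)
    } else {
      range <- c(floor(min(x) / bin_width), floor(max(x) / bin_width) + 1) *
        bin_width
    }
  }
  lo <- seq(range[1], range[2] - bin_width / 2, by = bin_width)
  counts <- vapply(lo, function(l) sum(x >= l & x < l + bin_width),
                   numeric(1))
  tibble::tibble(bin_lo = lo, bin_hi = lo + bin_width, count = counts)
}

#' Weekly blood-pressure extremes
#'
#' Maximum SBP and minimum DBP for each weekday present in the series,
#' keyed Monday-first (in-week variation, and Monday onset risk in
#' particular, is of clinical interest). A weekday occurring on several
#' dates pools all its readings.
#'
#' @param data BP series tibble.
#' @returns tibble with `weekday` (ordered factor Monday..Sunday, only
#'   days present), `max_sbp`, `min_dbp`, `n`.
#' @export
weekly_stats <- function(data) {
  check_bp_series(data)
  wd_levels <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
                 "Saturday", "Sunday")
  ## locale-independent weekday: 1970-01-05 was a Monday
  wd_idx <- (as.integer(as.Date(data$time) - as.Date("1970-01-05"))) %% 7L + 1L
  wd <- factor(wd_levels[wd_idx], levels = wd_levels, ordered = TRUE)
  tibble::tibble(weekday = wd, sbp = data$sbp, dbp = data$dbp) |>
    dplyr::group_by(.data$weekday) |>
    dplyr::summarise(max_sbp = max(.data$sbp), min_dbp = min(.data$dbp),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$weekday)
}

#' Body-mass index
#' @param weight weight in kg.
#' @param height height in m.
#' @returns BMI in kg/m^2.
#' @export
bmi <- function(weight, height) weight / height^2

#' Calorie expenditure from a step count
#' @param steps pedometer step count.
#' @param kcal_per_step conversion factor (default 0.04 kcal/step).
#' @returns kilocalories.
#' @export
calories_from_steps <- function(steps, kcal_per_step = 0.04) {
  steps * kcal_per_step
}

#' Line plot of a 24-hour BP series
#'
#' @param object BP series tibble (`time`, `sbp`, `dbp`).
#' @param ... unused.
#' @returns a ggplot of SBP and DBP over time with the nighttime window
#'   shaded.
#' @export
plot_bp_series <- function(object, ...) {
  check_bp_series(object)
  long <- tidyr::pivot_longer(object, c("sbp", "dbp"),
                              names_to = "measure", values_to = "mmHg")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mmHg,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = "BP [mmHg]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of a BP histogram
#'
#' @param data BP series tibble.
#' @param ... passed to [bp_histogram()].
#' @returns a ggplot.
#' @export
plot_bp_histogram <- function(data, ...) {
  h <- bp_histogram(data, ...)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_lo + (h$bin_hi - h$bin_lo) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = (h$bin_hi - h$bin_lo)[1] * 0.95,
                      fill = "steelblue") +
    ggplot2::labs(x = "BP [mmHg]", y = "Readings") +
    ggplot2::theme_minimal()
}
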