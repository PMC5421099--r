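## Signal containers and conditioning

#' Construct a PPG signal
#'
#' A `ppg_signal` is a tibble with columns `time` (seconds) and
#' `amplitude` (arbitrary units) plus a sampling-rate attribute. All
#' processing functions accept and return this container.
#'
#' @param amplitude numeric vector of samples.
#' @param fs sampling rate in Hz (the field standard for wrist sensors is
#'   100 Hz).
#' @param t0 optional start time (POSIXct or seconds offset); stored as an
#'   attribute, all `time` values are relative seconds.
#' @returns a `ppg_signal` tibble.
#' @export
#' @examples
#' ppg_signal(sin(2 * pi * seq(0, 5, by = 0.01)), fs = 100)
ppg_signal <- function(amplitude, fs, t0 = NULL) {
  stopifnot(is.numeric(amplitude), is.numeric(fs), fs > 0)
  out <- tibble::tibble(time = (seq_along(amplitude) - 1) / fs,
                        amplitude = as.numeric(amplitude))
  class(out) <- c("ppg_signal", class(out))
  attr(out, "fs") <- fs
  attr(out, "t0") <- t0
  out
}

new_apg_signal <- function(amplitude, fs, valid) {
  out <- tibble::tibble(time = (seq_along(amplitude) - 1) / fs,
                        amplitude = as.numeric(amplitude),
                        valid = valid)
  class(out) <- c("apg_signal", class(out))
  attr(out, "fs") <- fs
  out
}

#' Sampling rate of a signal
#' @param x a `ppg_signal` or `apg_signal`.
#' @returns sampling rate in Hz.
#' @export
signal_fs <- function(x) attr(x, "fs")

#' Band-pass filter a PPG signal
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass. The
#' default band (0.2-20 Hz) keeps the pulse fundamental (0.9-1.5 Hz at
#' rest) and the harmonics that carry the APG morphology essentially
#' untouched while removing baseline drift and the DC component; a
#' tighter high-pass measurably erodes the fundamental and biases the
#' wave heights.
#'
#' @param ppg a `ppg_signal`.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @returns a filtered `ppg_signal` of the same length.
#' @export
bandpass <- function(ppg, low = 0.2, high = 20) {
  stopifnot(inherits(ppg, "ppg_signal"))
  fs <- signal_fs(ppg)
  if (!(low > 0 && high > low && high < fs / 2)) {
    ppgbp_abort(
      sprintf("band [%g, %g] Hz outside (0, fs/2) = (0, %g) Hz", low, high, fs / 2),
      "ppgbp_error_input")
  }
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  ## explicit mean removal: a constant input maps to exact zeros and the
  ## recursive filter only sees the fluctuation around baseline
  x <- ppg$amplitude - mean(ppg$amplitude)
  n <- length(x)
  ## odd-symmetric reflection padding suppresses the forward-backward
  ## filter's edge transients (which otherwise masquerade as beats)
  np <- min(n - 1L, as.integer(2 * fs))
  left <- 2 * x[1L] - x[seq(np + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - np)]
  xf <- signal::filtfilt(bf, c(left, x, right))
  out <- ppg
  out$amplitude <- xf[seq(np + 1L, np + n)]
  out
}

#' Acceleration plethysmogram: second derivative of the PPG
#'
#' Computes the APG by smoothed polynomial differentiation: a
#' Savitzky-Golay filter fits a local quartic over a short window and
#' evaluates its second derivative at the centre. Raw double differencing
#' amplifies noise and blunts the small c/d/e waves; the local-polynomial
#' estimate is exact for polynomials up to the fit order and attenuates
#' the narrow APG lobes by under ~3% at 100 Hz.
#'
#' @param ppg a `ppg_signal` with at least 5 samples.
#' @param window odd window length in samples (default 7 at 100 Hz).
#' @param order polynomial order of the local fit (default 4).
#' @returns an `apg_signal` (a.u./s^2) of the same length; the
#'   half-window boundary samples are flagged `valid = FALSE` rather than
#'   extrapolated.
#' @export
second_derivative <- function(ppg, window = 7L, order = 4L) {
  stopifnot(inherits(ppg, "ppg_signal"))
  n <- nrow(ppg)
  if (n < max(5L, window)) {
    ppgbp_abort("signal too short for second derivative",
                "ppgbp_error_input")
  }
  fs <- signal_fs(ppg)
  acc <- signal::sgolayfilt(ppg$amplitude, p = order, n = window, m = 2,
                            ts = 1 / fs)
  half <- (window - 1L) %/% 2L
  valid <- rep(TRUE, n)
  valid[seq_len(half)] <- FALSE
  valid[seq.int(n - half + 1L, n)] <- FALSE
  new_apg_signal(acc, fs, valid)
}

#' Segment a conditioned PPG into beats
#'
#' Beats are anchored on the a-waves: the dominant positive APG peaks
#' (above half the 95th-percentile peak height, at least 300 ms apart).
#' Each beat onset is the pulse foot, i.e. the PPG minimum within 250 ms
#' before its a-wave, refined to sub-sample precision. Consecutive onsets
#' with an interval outside the physiologic range are dropped.
#'
#' @param ppg band-passed `ppg_signal`.
#' @param apg matching `apg_signal`.
#' @param min_period,max_period physiologic inter-onset bounds in seconds.
#' @returns a tibble with one row per beat: `beat`, `onset` (sample
#'   index), `onset_time` (interpolated seconds), `end` (sample index of
#'   the next onset), `period` (seconds). Zero rows when no beats are
#'   found (e.g. a flat signal).
#' @export
segment_beats <- function(ppg, apg, min_period = 0.3, max_period = 2.0) {
  stopifnot(inherits(ppg, "ppg_signal"), inherits(apg, "apg_signal"))
  fs <- signal_fs(ppg)
  y <- apg$amplitude
  y[!apg$valid] <- 0
  empty <- tibble::tibble(beat = integer(0), onset = integer(0),
                          onset_time = numeric(0), end = integer(0),
                          period = numeric(0))
  if (all(abs(y) < .Machine$double.eps^0.5) || nrow(ppg) < 3L) return(empty)
  mx <- extrema_with_prominence(y)
  pk <- mx$idx[y[mx$idx] > 0]
  if (!length(pk)) return(empty)
  thr <- 0.5 * stats::quantile(y[pk], 0.95, names = FALSE)
  pk <- pk[y[pk] >= thr]
  if (!length(pk)) return(empty)
  ## enforce minimal separation, keeping the higher peak
  keep <- integer(0)
  for (i in pk) {
    if (length(keep) && (i - keep[length(keep)]) / fs < min_period) {
      if (y[i] > y[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  ## pulse foot before each a-wave
  x <- ppg$amplitude
  onsets <- vapply(keep, function(i) {
    w <- max(1L, i - as.integer(round(0.25 * fs))):i
    w[which.min(x[w])]
  }, integer(1))
  onsets <- unique(onsets)
  if (length(onsets) < 2L) return(empty)
  onset_time <- vapply(onsets, function(i) {
    parabolic_refine(ppg$time, x, i, sign = -1)$t
  }, numeric(1))
  period <- diff(onset_time)
  ok <- period >= min_period & period <= max_period
  tibble::tibble(beat = seq_len(sum(ok)),
                 onset = onsets[-length(onsets)][ok],
                 onset_time = onset_time[-length(onset_time)][ok],
                 end = onsets[-1L][ok],
                 period = period[ok])
}

#' Pulse rate from segmented beats
#'
#' Beats per minute over the trailing window, computed from the mean
#' inter-onset interval of the beats falling in that window (the classic
#' "pulse counted from the pulse wave of the past minute").
#'
#' @param beats beat table from [segment_beats()].
#' @param window trailing window length in seconds (default 60).
#' @returns pulse rate in bpm, or `NA_real_` when fewer than two beat
#'   onsets fall inside the window (undefined, as opposed to zero).
#' @export
#' @examples
#' beats <- tibble::tibble(onset_time = seq(0, 59, by = 1))
#' pulse_rate(beats)  # 60 bpm
pulse_rate <- function(beats, window = 60) {
  on <- beats$onset_time
  if (length(on) < 2L) return(NA_real_)
  t_end <- max(on)
  on <- on[on > t_end - window]
  if (length(on) < 2L) return(NA_real_)
  60 * (length(on) - 1) / (max(on) - min(on))
}
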