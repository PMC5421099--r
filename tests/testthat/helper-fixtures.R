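## Shared fixtures, built in code at test time.

wave_names <- c("a", "b", "c", "d", "e")

## one subject + noiseless recording, memoised per seed
quick_recording <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1, duration = 10, noise_sd = 0, ...) {
    key <- paste(seed, duration, noise_sd, sep = "_")
    if (is.null(cache[[key]])) {
      subj <- generate_population(1, seed = seed, ...)
      rec <- synthesize_ppg(subj, duration = duration, noise_sd = noise_sd,
                            seed = seed)
      cache[[key]] <- list(subject = subj, signal = rec$signal,
                           truth = rec$truth)
    }
    cache[[key]]
  }
})

## run the standard conditioning chain
condition_chain <- function(signal) {
  f <- bandpass(signal)
  apg <- second_derivative(f)
  list(filtered = f, apg = apg, beats = segment_beats(f, apg))
}

## exhaustive best-subset search minimising BIC, via lm(); the
## independent oracle for stepwise selection
best_subset_bic <- function(data, target, candidates) {
  best <- list(bic = Inf, subset = character(0))
  for (k in 0:length(candidates)) {
    combs <- utils::combn(candidates, k, simplify = FALSE)
    for (s in combs) {
      fml <- stats::reformulate(if (length(s)) s else "1", response = target)
      b <- stats::BIC(stats::lm(fml, data = data))
      if (b < best$bic) best <- list(bic = b, subset = s)
    }
  }
  sort(best$subset)
}

## 24-h BP fixture with constant day/night values
constant_bp_series <- function(day_sbp = 130, day_dbp = 80,
                               night_sbp = 110, night_dbp = 70,
                               date = as.Date("2026-01-05")) {
  times <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
    seq(0, by = 30 * 60, length.out = 48)
  hr <- as.integer(format(times, "%H"))
  day <- hr >= 6 & hr < 22
  tibble::tibble(time = times,
                 sbp = ifelse(day, day_sbp, night_sbp),
                 dbp = ifelse(day, day_dbp, night_dbp))
}

## match ground-truth beats to detected beats by onset time; returns the
## index of the detected beat for each truth row (NA when unmatched)
match_beats <- function(truth, beats, tol = 0.020) {
  vapply(truth$onset_time, function(on) {
    d <- abs(beats$onset_time - on)
    j <- which.min(d)
    if (length(j) && d[j] <= tol) j else NA_integer_
  }, integer(1))
}
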