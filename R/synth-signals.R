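## Synthetic recordings: PPG with fiducial ground truth, PTT, 24-h BP

subject_template <- function(subject) {
  h <- vapply(WAVE_NAMES, function(w) subject[[paste0("morph_h_", w)]],
              numeric(1))
  mu <- vapply(WAVE_NAMES, function(w) subject[[paste0("morph_mu_", w)]],
               numeric(1))
  sg <- vapply(WAVE_NAMES, function(w) subject[[paste0("morph_sig_", w)]],
               numeric(1))
  beat_template(subject$heart_period, heights = h, mu_frac = mu, sigma = sg)
}

#' Synthesize a PPG recording with known fiducial ground truth
#'
#' Evaluates the subject's periodic beat model at the sampling grid, adds
#' white measurement noise, and records the analytic ground truth: the
#' onset of every complete beat and the a-e latencies and heights of the
#' noiseless waveform. A beat is complete when its onset and the next
#' onset both lie inside the record, with a 10%-of-period guard so the
#' closing beat's a-wave is inside too; partial boundary beats carry no
#' ground truth.
#'
#' @param subject one-row tibble from [generate_population()] (or a list
#'   with the same fields).
#' @param duration recording length in seconds; must cover at least 3
#'   heart periods.
#' @param fs sampling rate in Hz (default 100, the wrist-sensor rate).
#' @param noise_sd white-noise SD in signal units (default 0.005; the
#'   pulse envelope has unit amplitude).
#' @param seed optional integer seed for the noise.
#' @returns list with `signal` (a `ppg_signal` of exactly
#'   `floor(duration * fs)` samples) and `truth`, a tibble with one row
#'   per complete beat: `beat`, `onset_time` (s), `period`, `t_a` ..
#'   `t_e` (s from onset) and `h_a` .. `h_e` (a.u./s^2).
#' @export
#' @examples
#' subj <- generate_population(1, seed = 2)
#' rec <- synthesize_ppg(subj, duration = 10, noise_sd = 0)
#' nrow(rec$signal)  # 1000 samples at 100 Hz
synthesize_ppg <- function(subject, duration, fs = 100, noise_sd = 0.005,
                           seed = NULL) {
  subject <- as.list(tibble::as_tibble(subject)[1L, ])
  period <- subject$heart_period
  if (duration < 3 * period) {
    ppgbp_abort(sprintf(
      "duration %.3g s is shorter than 3 heart periods (%.3g s)",
      duration, 3 * period), "ppgbp_error_input")
  }
  tpl <- subject_template(subject)
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- beat_ppg(tpl, t)
  if (noise_sd > 0) {
    x <- x + with_seed_if(seed, rnorm(n, 0, noise_sd))
  }
  gt <- beat_ground_truth(tpl)
  onset0 <- gt$onset %% period
  onsets <- seq(onset0, duration, by = period)
  ## complete beats: onset and closing onset inside the record, with a
  ## 10%-of-period guard so the closing beat's a-wave (which marks the
  ## boundary) also lies inside
  complete <- onsets[onsets + 1.1 * period <= duration]
  truth <- tibble::tibble(beat = seq_along(complete),
                          onset_time = complete, period = period)
  for (wv in WAVE_NAMES) {
    truth[[paste0("t_", wv)]] <- gt$times[[wv]]
    truth[[paste0("h_", wv)]] <- gt$heights[[wv]]
  }
  list(signal = ppg_signal(x, fs = fs), truth = truth)
}

#' Synthesize pulse transit times from an SBP series
#'
#' PTT is generated as an affine-decreasing function of systolic pressure
#' plus Gaussian noise: `ptt = p0 - p1 * sbp + noise`. The magnitudes are
#' of the order typical for wrist-to-heart transit and are configurable;
#' with `noise_sd = 0` the correlation with SBP is exactly -1.
#'
#' @param sbp numeric vector of systolic pressures, mmHg.
#' @param noise_sd Gaussian noise SD in ms.
#' @param p0 intercept in ms (default 350).
#' @param p1 slope in ms per mmHg (default 1).
#' @param seed optional integer seed.
#' @returns numeric vector of PTT values, ms.
#' @export
#' @examples
#' synthesize_ptt(c(110, 120, 130))  # strictly decreasing
synthesize_ptt <- function(sbp, noise_sd = 0, p0 = 350, p1 = 1, seed = NULL) {
  if (!length(sbp)) {
    ppgbp_abort("empty SBP series", "ppgbp_error_input")
  }
  ptt <- p0 - p1 * sbp
  if (noise_sd > 0) {
    ptt <- ptt + with_seed_if(seed, rnorm(length(sbp), 0, noise_sd))
  }
  ptt
}

DIPPING_PATTERNS <- c("riser", "nondipper", "dipper", "extreme-dipper")

#' Synthesize a 24-hour blood-pressure series with a prescribed dipping pattern
#'
#' Generates one reading every 30 minutes for a day (48 readings). A
#' nocturnal decline is drawn from the interior of the requested
#' pattern's band (riser -8%, nondipper 2-8%, dipper 12-18%,
#' extreme-dipper 22-28%) and the day/night readings are recentred so the
#' realised window means hit their targets exactly; the generated series
#' therefore classifies back to the requested pattern by construction.
#'
#' @param pattern one of `"dipper"`, `"nondipper"`, `"extreme-dipper"`,
#'   `"riser"`.
#' @param day_mean target daytime mean SBP, mmHg (80-200).
#' @param seed optional integer seed.
#' @param date calendar date of the series (the day starts at 00:00 local
#'   time).
#' @param noise_sd reading-to-reading SD around the window mean, mmHg.
#' @returns a tibble (`time` POSIXct, `sbp`, `dbp`) of 48 readings.
#' @seealso [classify_dipping()]
#' @export
synthesize_bp_series <- function(pattern, day_mean = 120, seed = NULL,
                                 date = as.Date("2026-01-05"),
                                 noise_sd = 4) {
  pattern <- match.arg(pattern, DIPPING_PATTERNS)
  if (!(day_mean >= 80 && day_mean <= 200)) {
    ppgbp_abort("`day_mean` must lie in [80, 200] mmHg", "ppgbp_error_input")
  }
  with_seed_if(seed, {
    decline <- switch(pattern,
      "riser" = runif(1, -12, -4),
      "nondipper" = runif(1, 2, 8),
      "dipper" = runif(1, 12, 18),
      "extreme-dipper" = runif(1, 22, 28))
    night_mean <- day_mean * (1 - decline / 100)
    times <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
      seq(0, by = 30 * 60, length.out = 48L)
    hr <- as.integer(format(times, "%H"))
    is_day <- hr >= 6L & hr < 22L
    target <- ifelse(is_day, day_mean, night_mean)
    sbp <- target + rnorm(48L, 0, noise_sd)
    ## recentre each window so the realised means match the construction
    sbp[is_day] <- sbp[is_day] - mean(sbp[is_day]) + day_mean
    sbp[!is_day] <- sbp[!is_day] - mean(sbp[!is_day]) + night_mean
    dbp_day <- day_mean - 45
    dbp <- ifelse(is_day, dbp_day, dbp_day * (1 - decline / 100)) +
      rnorm(48L, 0, noise_sd / 2)
    dbp[is_day] <- dbp[is_day] - mean(dbp[is_day]) + dbp_day
    dbp[!is_day] <- dbp[!is_day] - mean(dbp[!is_day]) +
      dbp_day * (1 - decline / 100)
    dbp <- pmin(dbp, sbp - 15)
    tibble::tibble(time = times, sbp = sbp, dbp = dbp)
  })
}

#' Simulate a cohort feature table through the full waveform pipeline
#'
#' For every subject of a population, synthesizes a PPG recording, runs
#' the standard conditioning chain (band-pass, APG, beat segmentation,
#' fiducial detection) and computes the 20-feature vector. This is the
#' workhorse for end-to-end evaluation on data with known ground truth.
#'
#' @param population tibble from [generate_population()].
#' @param duration per-subject recording length in seconds.
#' @param fs sampling rate, Hz.
#' @param noise_sd waveform noise SD (signal units).
#' @param seed optional integer seed (controls all per-subject noise).
#' @returns feature tibble with `subject_id`, the 20 features and the
#'   `true_sbp` / `true_dbp` targets; subjects whose recording yields no
#'   fully valid beat are dropped with a warning.
#' @export
simulate_feature_table <- function(population, duration = 10, fs = 100,
                                   noise_sd = 0.005, seed = NULL) {
  run <- function() {
    rows <- purrr::map(seq_len(nrow(population)), function(i) {
      subj <- population[i, ]
      rec <- synthesize_ppg(subj, duration = duration, fs = fs,
                            noise_sd = noise_sd)
      fv <- tryCatch(extract_features(rec$signal, subject = subj),
                     ppgbp_error = function(e) NULL)
      if (is.null(fv)) return(NULL)
      dplyr::bind_cols(tibble::tibble(subject_id = subj$subject_id), fv,
                       tibble::tibble(true_sbp = subj$true_sbp,
                                      true_dbp = subj$true_dbp))
    })
    dropped <- sum(vapply(rows, is.null, logical(1)))
    if (dropped > 0) {
      warning(sprintf("%d of %d subjects yielded no valid beats and were dropped",
                      dropped, nrow(population)), call. = FALSE)
    }
    dplyr::bind_rows(rows)
  }
  with_seed_if(seed, run())
}
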