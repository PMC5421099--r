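## Feature vector assembly

#' Names of the 20 estimation features
#'
#' Wave heights `a` .. `e`, latencies `T_a` .. `T_e`, height ratios
#' `b_a` .. `e_a`, the APG index, pulse rate `pr`, and the questionnaire
#' covariates `height` (m), `weight` (kg), `age` (years) and `sex`
#' (male 0, female 1).
#'
#' @returns character vector of length 20.
#' @export
feature_names <- function() {
  c(WAVE_NAMES, paste0("T_", WAVE_NAMES),
    c("b_a", "c_a", "d_a", "e_a"), "apg_index", "pr",
    "height", "weight", "age", "sex")
}

#' Compute the feature vector for one measurement window
#'
#' Aggregates per-beat fiducials into the 20-feature vector: heights and
#' latencies are the medians over the fully valid beats (robust to missed
#' detections), ratios and the APG index are computed from the aggregated
#' heights, and the questionnaire covariates are passed through.
#'
#' @param fiducials per-beat table from [detect_fiducials()].
#' @param pr pulse rate in bpm, see [pulse_rate()].
#' @param subject one-row tibble or list carrying `height`, `weight`,
#'   `age`, `sex`.
#' @returns a one-row tibble with the columns of [feature_names()].
#' @export
compute_features <- function(fiducials, pr, subject) {
  ok <- rowSums(!as.matrix(fiducials[paste0("ok_", WAVE_NAMES)])) == 0
  if (!any(ok)) {
    ppgbp_abort("no fully valid beat in the window: no features",
                "ppgbp_error_no_features")
  }
  fid <- fiducials[ok, ]
  subject <- as.list(tibble::as_tibble(subject)[1L, ])
  agg <- lapply(WAVE_NAMES, function(wv) {
    c(stats::median(fid[[paste0("h_", wv)]]),
      stats::median(fid[[paste0("t_", wv)]]))
  })
  h <- setNames(vapply(agg, `[`, numeric(1), 1L), WAVE_NAMES)
  tt <- setNames(vapply(agg, `[`, numeric(1), 2L), WAVE_NAMES)
  out <- tibble::tibble(
    a = h[["a"]], b = h[["b"]], c = h[["c"]], d = h[["d"]], e = h[["e"]],
    T_a = tt[["a"]], T_b = tt[["b"]], T_c = tt[["c"]], T_d = tt[["d"]],
    T_e = tt[["e"]],
    b_a = h[["b"]] / h[["a"]], c_a = h[["c"]] / h[["a"]],
    d_a = h[["d"]] / h[["a"]], e_a = h[["e"]] / h[["a"]],
    apg_index = apg_index(h[["a"]], h[["b"]], h[["c"]], h[["d"]]),
    pr = pr,
    height = subject$height, weight = subject$weight,
    age = subject$age, sex = subject$sex)
  out[feature_names()]
}

#' Extract the feature vector from a raw PPG recording
#'
#' Convenience chain: band-pass conditioning, APG computation, beat
#' segmentation, fiducial detection, pulse rate, and feature aggregation
#' over the window.
#'
#' @param ppg raw `ppg_signal`.
#' @param subject one-row tibble with the questionnaire covariates.
#' @param band band-pass edges in Hz.
#' @param ... passed on to [detect_fiducials()].
#' @returns one-row feature tibble, see [compute_features()].
#' @export
#' @examples
#' subj <- generate_population(1, seed = 5)
#' rec <- synthesize_ppg(subj, duration = 10, noise_sd = 0)
#' extract_features(rec$signal, subj)
extract_features <- function(ppg, subject, band = c(0.2, 20), ...) {
  filtered <- bandpass(ppg, band[1], band[2])
  apg <- second_derivative(filtered)
  beats <- segment_beats(filtered, apg)
  if (!nrow(beats)) {
    ppgbp_abort("no beats found in recording", "ppgbp_error_no_features")
  }
  fid <- detect_fiducials(apg, beats, ...)
  compute_features(fid, pr = pulse_rate(beats), subject = subject)
}
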