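## Synthetic beat model
##
## One beat is a trigonometric polynomial with period equal to the heart
## period. The waveform is designed in the acceleration (APG) domain: five
## localised Gaussian lobes with alternating signs (the a-e waves) plus a
## slow envelope term, projected onto the first `n_harmonics` harmonics.
## The PPG is the exact double antiderivative of that series, so PPG and
## APG are both closed-form and the fiducial ground truth can be read off
## a fine grid of the analytic APG.

WAVE_NAMES <- c("a", "b", "c", "d", "e")

## reference APG lobe heights (a.u./s^2), lobe centres (fraction of the
## heart period) and lobe widths (seconds, fixed across subjects)
MORPH_REF_HEIGHT <- c(a = 1560, b = -1020, c = 450, d = -420, e = 330)
MORPH_REF_MU     <- c(a = 0.10, b = 0.20, c = 0.32, d = 0.42, e = 0.72)
MORPH_REF_SIGMA  <- c(a = 0.028, b = 0.026, c = 0.024, d = 0.024, e = 0.030)
MORPH_ENVELOPE   <- 1        # amplitude of the sin^2 pulse envelope (a.u.)
MORPH_HARMONICS  <- 16L      # harmonics kept in the beat series

#' Build the harmonic coefficients of one synthetic beat
#'
#' Internal constructor used by [synthesize_ppg()]. Returns the complex
#' Fourier coefficients of the PPG and of its exact second derivative.
#'
#' @param heart_period heart period in seconds.
#' @param heights named numeric of APG lobe heights for waves a-e.
#' @param mu_frac lobe centres as fractions of the heart period.
#' @param sigma lobe widths in seconds.
#' @param envelope amplitude of the slow pulse envelope.
#' @param n_harmonics number of harmonics retained.
#' @returns list with `period`, `ppg_coef`, `apg_coef` (complex vectors,
#'   harmonic 1..M of `exp(2i*pi*m*t/period)`).
#' @keywords internal
#' @noRd
beat_template <- function(heart_period,
                          heights = MORPH_REF_HEIGHT,
                          mu_frac = MORPH_REF_MU,
                          sigma = MORPH_REF_SIGMA,
                          envelope = MORPH_ENVELOPE,
                          n_harmonics = MORPH_HARMONICS) {
  stopifnot(length(heights) == 5L, length(mu_frac) == 5L, length(sigma) == 5L,
            heart_period > 0)
  N <- 4096L
  tg <- seq(0, heart_period, length.out = N + 1L)[seq_len(N)]
  mu <- mu_frac * heart_period
  apg <- envelope * 2 * pi^2 / heart_period^2 * cos(2 * pi * tg / heart_period)
  for (k in seq_len(5L)) {
    apg <- apg + heights[k] * exp(-(tg - mu[k])^2 / (2 * sigma[k]^2))
  }
  ## harmonic projection; the DC term is dropped (a periodic signal has a
  ## zero-mean second derivative), which shifts all lobes by a common offset
  co <- stats::fft(apg) / N
  m <- seq_len(n_harmonics)
  apg_coef <- co[m + 1L]
  ppg_coef <- -apg_coef / (2 * pi * m / heart_period)^2
  list(period = heart_period, ppg_coef = ppg_coef, apg_coef = apg_coef)
}

## evaluate a harmonic series at times t (vectorised over t)
eval_harmonics <- function(coef, t, period) {
  v <- numeric(length(t))
  for (m in seq_along(coef)) {
    v <- v + 2 * Re(coef[m] * exp(2i * pi * m * t / period))
  }
  v
}

beat_ppg <- function(template, t) {
  eval_harmonics(template$ppg_coef, t, template$period)
}

beat_apg <- function(template, t) {
  eval_harmonics(template$apg_coef, t, template$period)
}

#' Analytic fiducial ground truth of a beat template
#'
#' Locates the beat onset (the PPG foot: the signal minimum within 250 ms
#' before the a-wave) and the a-e extrema of the analytic APG on a fine
#' time grid, using the same prominence rule as the detector.
#'
#' @param template result of `beat_template()`.
#' @param dt fine-grid step in seconds.
#' @returns list with `onset` (seconds from the template origin), `times`
#'   (named, seconds from onset) and `heights` (named, a.u./s^2). Waves
#'   whose lobe is suppressed come back as `NA`.
#' @keywords internal
#' @noRd
beat_ground_truth <- function(template, dt = 2e-4) {
  period <- template$period
  t <- seq(-0.25, period, by = dt)
  ap <- beat_apg(template, t)
  pp <- beat_ppg(template, t)
  mx <- extrema_with_prominence(ap)
  if (!length(mx$idx)) {
    ppgbp_abort("degenerate beat template: APG has no maxima",
                "ppgbp_error_config")
  }
  pos <- mx$idx[t[mx$idx] > 0 & t[mx$idx] <= 0.9 * period]
  ia <- pos[which.max(ap[pos])]
  w <- which(t >= t[ia] - 0.25 & t <= t[ia])
  io <- w[which.min(pp[w])]
  onset <- t[io]
  idx <- select_fiducials(t, ap, onset = onset, period = period)
  times <- setNames(t[idx] - onset, WAVE_NAMES)
  heights <- setNames(ap[idx], WAVE_NAMES)
  times[is.na(idx)] <- NA_real_
  heights[is.na(idx)] <- NA_real_
  list(onset = onset, times = times, heights = heights)
}
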