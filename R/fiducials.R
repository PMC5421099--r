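## APG fiducial detection
##
## The a-e waves are the chronological alternating extrema of the APG
## within one beat. `a` is the dominant maximum after the beat onset, `b`
## the first minimum after it; `c` and `d` are the next maximum/minimum
## inside 0.6 heart periods from onset, and `e` the following maximum,
## searched out to 0.75 periods (the diastolic wave may fall beyond the
## systolic search horizon, and an accepted maximum beyond 0.6 periods is
## taken as `e` even when `c`/`d` are missing). Extrema must clear a
## minimal topographic prominence, a fixed fraction of the beat's APG
## peak-to-peak range, which suppresses noise ripples.

## local maxima of x with their topographic prominence
extrema_with_prominence <- function(x) {
  n <- length(x)
  d <- diff(x)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(idx)) return(list(idx = integer(0), prom = numeric(0)))
  prom <- vapply(idx, function(i) {
    h <- x[i]
    lb <- h; j <- i
    while (j > 1L && x[j] <= h) { j <- j - 1L; if (x[j] < lb) lb <- x[j] }
    rb <- h; j <- i
    while (j < n && x[j] <= h) { j <- j + 1L; if (x[j] < rb) rb <- x[j] }
    h - max(lb, rb)
  }, numeric(1))
  list(idx = idx, prom = prom)
}

## chronological alternating selection of the a-e extrema.
## t: time axis; ap: APG samples; returns named integer indices (NA = not found)
select_fiducials <- function(t, ap, onset, period,
                             prominence_frac = 0.02,
                             horizon = 0.6, horizon_e = 0.75) {
  res <- setNames(rep(NA_integer_, 5L), WAVE_NAMES)
  win <- which(t > onset & t <= onset + horizon_e * period)
  if (length(win) < 3L) return(res)
  p2p <- diff(range(ap[win]))
  if (!is.finite(p2p) || p2p <= 0) return(res)
  mx <- extrema_with_prominence(ap)
  mn <- extrema_with_prominence(-ap)
  thr <- prominence_frac * p2p
  keep_mx <- mx$idx[mx$idx %in% win & mx$prom >= thr]
  keep_mn <- mn$idx[mn$idx %in% win & mn$prom >= thr]
  if (!length(keep_mx)) return(res)
  ia <- keep_mx[which.max(ap[keep_mx])]
  res["a"] <- ia
  bs <- keep_mn[keep_mn > ia]
  if (!length(bs)) return(res)
  res["b"] <- bs[1L]
  lim <- onset + horizon * period
  cs <- keep_mx[keep_mx > res["b"] & t[keep_mx] <= lim]
  if (length(cs)) {
    res["c"] <- cs[1L]
    ds <- keep_mn[keep_mn > res["c"] & t[keep_mn] <= lim]
    if (length(ds)) res["d"] <- ds[1L]
  }
  last <- max(res[c("b", "c", "d")], na.rm = TRUE)
  ## when c is missing, a maximum can only be e beyond the systolic horizon
  e_floor <- if (is.na(res["c"])) lim else t[res["c"]]
  es <- keep_mx[keep_mx > last & t[keep_mx] > e_floor &
                  t[keep_mx] <= onset + horizon_e * period]
  if (length(es)) res["e"] <- es[1L]
  res
}

## sub-sample refinement of an extremum by parabolic interpolation
## sign = +1 for maxima, -1 for minima; returns list(t, h)
parabolic_refine <- function(t, y, i, sign = 1) {
  if (i <= 1L || i >= length(y)) return(list(t = t[i], h = y[i]))
  ys <- sign * y[(i - 1L):(i + 1L)]
  den <- ys[1] - 2 * ys[2] + ys[3]
  d <- if (den == 0) 0 else (ys[1] - ys[3]) / (2 * den)
  d <- max(min(d, 0.5), -0.5)
  h <- ys[2] - 0.25 * (ys[1] - ys[3]) * d
  step <- t[i + 1L] - t[i]
  list(t = t[i] + d * step, h = sign * h)
}

#' Detect APG fiducial waves for each beat
#'
#' Locates the a, b, c, d and e waves of the acceleration plethysmogram
#' within each segmented beat and reports their latencies from the beat
#' onset together with their heights. Wave times and heights are refined
#' to sub-sample precision by parabolic interpolation; waves that cannot
#' be found (e.g. a merged dicrotic structure) are returned as `NA` with
#' their validity flag set to `FALSE`.
#'
#' @param apg an `apg_signal`, see [second_derivative()].
#' @param beats beat table from [segment_beats()].
#' @param prominence_frac minimal prominence of an accepted extremum as a
#'   fraction of the beat's APG peak-to-peak range. Default 0.02.
#' @param horizon search horizon for the a-d waves, as a fraction of the
#'   beat period. Default 0.6.
#' @param horizon_e extended search horizon for the e wave. Default 0.75.
#' @returns a tibble with one row per beat: `beat`, `onset_time`,
#'   `period`, validity flags `ok_a` .. `ok_e`, latencies `t_a` .. `t_e`
#'   (seconds from onset) and heights `h_a` .. `h_e` (a.u./s^2).
#' @seealso [compute_features()] for the per-window feature vector.
#' @export
#' @examples
#' subj <- generate_population(1, seed = 1)
#' rec <- synthesize_ppg(subj, duration = 10, noise_sd = 0)
#' ppg <- bandpass(rec$signal)
#' apg <- second_derivative(ppg)
#' beats <- segment_beats(ppg, apg)
#' detect_fiducials(apg, beats)
detect_fiducials <- function(apg, beats, prominence_frac = 0.02,
                             horizon = 0.6, horizon_e = 0.75) {
  stopifnot(inherits(apg, "apg_signal"))
  fs <- signal_fs(apg)
  t <- apg$time
  y <- apg$amplitude
  rows <- purrr::map(seq_len(nrow(beats)), function(j) {
    onset_time <- beats$onset_time[j]
    period <- beats$period[j]
    lo <- beats$onset[j]
    hi <- min(length(y), beats$onset[j] +
                as.integer(ceiling(horizon_e * period * fs)) + 1L)
    seg <- lo:hi
    idx <- select_fiducials(t[seg], y[seg], onset = onset_time,
                            period = period,
                            prominence_frac = prominence_frac,
                            horizon = horizon, horizon_e = horizon_e)
    out <- list(beat = j, onset_time = onset_time, period = period)
    for (k in seq_along(WAVE_NAMES)) {
      wv <- WAVE_NAMES[k]
      if (is.na(idx[wv])) {
        out[[paste0("ok_", wv)]] <- FALSE
        out[[paste0("t_", wv)]] <- NA_real_
        out[[paste0("h_", wv)]] <- NA_real_
      } else {
        sgn <- if (wv %in% c("a", "c", "e")) 1 else -1
        ref <- parabolic_refine(t[seg], y[seg], idx[wv], sign = sgn)
        out[[paste0("ok_", wv)]] <- TRUE
        out[[paste0("t_", wv)]] <- ref$t - onset_time
        out[[paste0("h_", wv)]] <- ref$h
      }
    }
    tibble::as_tibble(out)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    ppgbp_abort("no beats supplied: no fiducials to detect",
                "ppgbp_error_no_fiducials")
  }
  out
}

#' APG index
#'
#' The composite vascular-state ratio `(c + d - b) / a` computed from the
#' four APG wave heights. Scale-invariant: multiplying all heights by a
#' common factor leaves it unchanged.
#'
#' @param a,b,c,d APG wave heights (a.u./s^2); vectors are recycled by the
#'   usual rules.
#' @returns numeric vector of APG index values.
#' @export
#' @examples
#' apg_index(a = 1, b = -0.8, c = 0.1, d = -0.3)  # 0.6
apg_index <- function(a, b, c, d) {
  if (any(a == 0, na.rm = TRUE)) {
    ppgbp_abort("degenerate beat: a-wave height is zero, APG index undefined",
                "ppgbp_error_degenerate_beat")
  }
  (c + d - b) / a
}
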