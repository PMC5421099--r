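## Conventional pulse-transit-time baseline
##
## The classic cuffless surrogate: blood-pressure variation (BPV) is
## regressed on pulse-transit-time variation (PTTV), both measured as
## deviations from a reference reading (the first sample of the series).
## The baseline predicts absolute pressure by adding the fitted deviation
## to the reference pressure.

#' Fit the PTT simple-regression baseline
#'
#' Deviations are formed from the first reading of each series (whose
#' BPV and PTTV are therefore 0 by construction) and BPV is regressed on
#' PTTV by simple least squares.
#'
#' @param ptt PTT series, ms.
#' @param bp matching BP series, mmHg.
#' @returns a `ptt_baseline` with `slope` (mmHg/ms), `intercept` (mmHg),
#'   `reference_bp` and `reference_ptt`.
#' @export
#' @examples
#' fit_ptt_baseline(ptt = c(300, 299, 298), bp = c(120, 122, 124))$slope # -2
fit_ptt_baseline <- function(ptt, bp) {
  if (length(ptt) != length(bp) || length(ptt) < 3L) {
    ppgbp_abort("need >= 3 paired (ptt, bp) readings", "ppgbp_error_input")
  }
  pttv <- ptt - ptt[1L]
  bpv <- bp - bp[1L]
  if (stats::var(pttv) == 0) {
    ppgbp_abort("zero-variance PTTV: baseline is degenerate",
                "ppgbp_error_degenerate_baseline")
  }
  fit <- stats::lm.fit(cbind(1, pttv), bpv)
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 reference_bp = bp[1L], reference_ptt = ptt[1L],
                 n = length(ptt)),
            class = "ptt_baseline")
}

#' Predict blood pressure from the PTT baseline
#'
#' `bp = reference_bp + intercept + slope * (ptt - reference_ptt)`.
#'
#' @param object a `ptt_baseline`.
#' @param ptt PTT values, ms. May also be a data frame with a `ptt`
#'   column.
#' @param ... unused.
#' @returns numeric vector of predicted BP, mmHg.
#' @export
predict.ptt_baseline <- function(object, ptt, ...) {
  if (is.data.frame(ptt)) ptt <- ptt$ptt
  object$reference_bp + object$intercept +
    object$slope * (ptt - object$reference_ptt)
}

#' @export
print.ptt_baseline <- function(x, ...) {
  cat(sprintf("<ptt_baseline> slope %.3g mmHg/ms, intercept %.3g mmHg, n = %d\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}
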