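## Evaluation protocols and error metrics
##
## Error sign convention, used throughout: error = estimated - measured.

new_bp_eval <- function(predictions, method = "unknown") {
  err <- predictions$estimated - predictions$measured
  r <- if (stats::sd(predictions$measured) == 0 ||
           stats::sd(predictions$estimated) == 0) {
    NA_real_
  } else {
    stats::cor(predictions$measured, predictions$estimated)
  }
  per_subject <- if ("subject_id" %in% names(predictions)) {
    predictions |>
      dplyr::mutate(error = .data$estimated - .data$measured) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(mean_error = mean(.data$error),
                       sd_error = stats::sd(.data$error),
                       n = dplyr::n(), .groups = "drop")
  } else {
    NULL
  }
  structure(list(r = r,
                 mean_error = mean(err),
                 sd_error = stats::sd(err),
                 n = nrow(predictions),
                 r_undefined = is.na(r),
                 predictions = predictions,
                 per_subject = per_subject,
                 method = method),
            class = "bp_eval")
}

#' Error metrics for blood-pressure estimates
#'
#' The reported triplet: Pearson correlation between measured and
#' estimated values, mean error and standard deviation of errors
#' (sample SD, n - 1 denominator), with errors defined as
#' `estimated - measured`. When subject identifiers are supplied a
#' per-subject breakdown (mean and SD of errors per subject) is attached.
#'
#' @param measured measured BP, mmHg.
#' @param estimated estimated BP, mmHg (same length).
#' @param subject_id optional subject identifier per observation.
#' @returns a `bp_eval`; see [glance.bp_eval()] and [tidy.bp_eval()].
#'   When either input has zero variance the correlation is undefined and
#'   flagged (`r_undefined`).
#' @export
#' @examples
#' ev <- error_metrics(c(100, 110, 120), c(102, 112, 118))
#' glance(ev)  # mean error 2/3, sd error sqrt(16/3)
error_metrics <- function(measured, estimated, subject_id = NULL) {
  if (length(measured) != length(estimated) || length(measured) < 2L) {
    ppgbp_abort("need equal-length vectors with n >= 2", "ppgbp_error_input")
  }
  preds <- tibble::tibble(measured = measured, estimated = estimated)
  if (!is.null(subject_id)) preds$subject_id <- subject_id
  new_bp_eval(preds)
}

#' Leave-one-out cross-validation of an estimation method
#'
#' Each measurement is predicted by a model fitted on the remaining
#' n - 1; the report is computed on the pooled predictions. Three fitters
#' are available: `"stepwise"` (feature selection re-run inside every
#' fold), `"ols"` (fixed feature set), and `"ptt"` (the simple-regression
#' transit-time baseline using the `ptt` column).
#'
#' @param data feature table with the target column (and `ptt` for the
#'   baseline; `subject_id` if present feeds the per-subject breakdown).
#' @param target target column name, mmHg.
#' @param method `"stepwise"`, `"ols"` or `"ptt"`.
#' @param candidates candidate (or, for `"ols"`, fixed) feature names;
#'   default: all 20 features present in `data`.
#' @param alpha_in,alpha_out,criterion stepwise settings, see
#'   [stepwise_select()].
#' @returns a `bp_eval` of the pooled out-of-fold predictions.
#' @export
loocv <- function(data, target = "true_sbp",
                  method = c("stepwise", "ols", "ptt"),
                  candidates = NULL, alpha_in = 0.05, alpha_out = 0.10,
                  criterion = "pvalue") {
  method <- match.arg(method)
  n <- nrow(data)
  if (n < 3L) ppgbp_abort("need n >= 3 for LOOCV", "ppgbp_error_input")
  y <- data[[target]]
  estimated <- numeric(n)

  if (method == "ptt") {
    ptt <- data[["ptt"]]
    if (is.null(ptt)) {
      ppgbp_abort("`ptt` column required for the PTT baseline",
                  "ppgbp_error_input")
    }
    for (i in seq_len(n)) {
      fit <- tryCatch(
        fit_ptt_baseline(ptt[-i], y[-i]),
        ppgbp_error = function(e) {
          ppgbp_abort(sprintf("LOOCV fold %d failed: %s", i,
                              conditionMessage(e)),
                      "ppgbp_error_fold")
        })
      estimated[i] <- predict(fit, ptt[i])
    }
  } else {
    if (is.null(candidates)) {
      candidates <- intersect(feature_names(), names(data))
    }
    dg <- design_gram(data, target, candidates)
    cand_idx <- seq_along(candidates) + 1L
    for (i in seq_len(n)) {
      zi <- dg$Z[i, ]
      Gi <- dg$G - tcrossprod(zi)
      gi <- dg$g - zi * y[i]
      yyi <- dg$yy - y[i]^2
      res <- if (method == "stepwise") {
        stepwise_gram(Gi, gi, yyi, n - 1L, cand_idx,
                      alpha_in = alpha_in, alpha_out = alpha_out,
                      criterion = criterion)
      } else {
        list(selected = cand_idx,
             fit = gram_fit(Gi, gi, yyi, n - 1L, c(1L, cand_idx)))
      }
      if (is.null(res$fit)) {
        ppgbp_abort(sprintf("LOOCV fold %d failed: singular fit", i),
                    "ppgbp_error_fold")
      }
      estimated[i] <- sum(res$fit$beta * zi[c(1L, res$selected)])
    }
  }
  preds <- tibble::tibble(measured = y, estimated = estimated)
  if (!is.null(data[["subject_id"]])) preds$subject_id <- data$subject_id
  new_bp_eval(preds, method = method)
}

#' Static-feature ablation study
#'
#' Runs LOOCV twice: once with the full candidate set and once with the
#' questionnaire covariates (height, weight, age, sex) removed, to
#' quantify how much of the estimate rests on personal information
#' rather than pulse-wave dynamics.
#'
#' @param data feature table.
#' @param target target column name.
#' @param candidates full candidate set (default: all features present).
#' @param ... passed to [loocv()].
#' @returns list with `full` and `ablated` (`bp_eval` objects) and
#'   `ablated_candidates`.
#' @export
ablation_static_features <- function(data, target = "true_sbp",
                                     candidates = NULL, ...) {
  if (is.null(candidates)) {
    candidates <- intersect(feature_names(), names(data))
  }
  static <- c("height", "weight", "age", "sex")
  ablated <- setdiff(candidates, static)
  list(full = loocv(data, target, method = "stepwise",
                    candidates = candidates, ...),
       ablated = loocv(data, target, method = "stepwise",
                       candidates = ablated, ...),
       ablated_candidates = ablated)
}

#' @export
print.bp_eval <- function(x, ...) {
  cat(sprintf("<bp_eval> n = %d: r = %.3f, mean error = %.2f mmHg, SD = %.2f mmHg\n",
              x$n, x$r, x$mean_error, x$sd_error))
  invisible(x)
}

#' One-row summary of an evaluation report
#'
#' @param x a `bp_eval`.
#' @param ... unused.
#' @returns tibble with `r`, `mean_error`, `sd_error`, `n`.
#' @exportS3Method generics::glance
glance.bp_eval <- function(x, ...) {
  tibble::tibble(r = x$r, mean_error = x$mean_error,
                 sd_error = x$sd_error, n = x$n)
}

#' Per-subject breakdown of an evaluation report
#'
#' @param x a `bp_eval`.
#' @param ... unused.
#' @returns tibble with one row per subject (`subject_id`, `mean_error`,
#'   `sd_error`, `n`) when subject ids were supplied, otherwise the
#'   pooled one-row summary.
#' @exportS3Method generics::tidy
tidy.bp_eval <- function(x, ...) {
  if (is.null(x$per_subject)) glance.bp_eval(x) else x$per_subject
}

#' Scatter plot of estimated vs measured blood pressure
#'
#' @param object a `bp_eval`.
#' @param ... unused.
#' @returns a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bp_eval <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$measured, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Measured SBP [mmHg]", y = "Estimated SBP [mmHg]",
                  subtitle = sprintf("r = %.2f, mean error %.2f mmHg, SD %.2f mmHg",
                                     object$r, object$mean_error,
                                     object$sd_error)) +
    ggplot2::theme_minimal()
}
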