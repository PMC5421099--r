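## Multiple regression with stepwise selection
##
## The estimator is the linear model
##   y = u0 + u1 x1 + ... + up xp
## with y the blood pressure target and x_i the selected features. The
## feature subset is chosen by bidirectional stepwise selection, either
## on partial-F p-values (enter when p < alpha_in, drop when
## p > alpha_out) or by greedy BIC descent. Fits are computed from the
## Gram matrix, which makes leave-one-out loops cheap via rank-one
## downdates.

## Gram-matrix least squares --------------------------------------------
## G = Z'Z for Z = [1 X], g = Z'y, yy = y'y. `cols` indexes into Z and
## always contains 1 (the intercept).
gram_fit <- function(G, g, yy, n, cols) {
  Gs <- G[cols, cols, drop = FALSE]
  R <- tryCatch(chol(Gs), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- backsolve(R, forwardsolve(t(R), g[cols]))
  rss <- max(yy - sum(beta * g[cols]), 0)
  df <- n - length(cols)
  sigma2 <- if (df > 0) rss / df else NA_real_
  XtXinv_diag <- rowSums(backsolve(R, diag(length(cols)))^2)
  se <- sqrt(sigma2 * XtXinv_diag)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, rss = rss, sigma2 = sigma2, se = se, t = tval,
       p = pval, df = df)
}

gram_bic <- function(rss, n, k) {
  ## gaussian-likelihood BIC up to a constant, consistent with stats::BIC
  n * log(2 * pi * rss / n) + n + (k + 1) * log(n)
}

stepwise_gram <- function(G, g, yy, n, candidates, alpha_in = 0.05,
                          alpha_out = 0.10, criterion = "pvalue",
                          max_steps = 100L) {
  sel <- integer(0)
  fit <- gram_fit(G, g, yy, n, 1L)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    ## forward
    pool <- setdiff(candidates, sel)
    if (length(pool) && n > length(sel) + 2L) {
      if (criterion == "pvalue") {
        pv <- vapply(pool, function(j) {
          f <- gram_fit(G, g, yy, n, c(1L, sel, j))
          if (is.null(f) || !is.finite(f$p[length(f$p)])) 1 else f$p[length(f$p)]
        }, numeric(1))
        if (min(pv) < alpha_in) {
          sel <- c(sel, pool[which.min(pv)])
          changed <- TRUE
        }
      } else {
        cur <- gram_fit(G, g, yy, n, c(1L, sel))
        bic0 <- gram_bic(cur$rss, n, length(sel))
        bics <- vapply(pool, function(j) {
          f <- gram_fit(G, g, yy, n, c(1L, sel, j))
          if (is.null(f)) Inf else gram_bic(f$rss, n, length(sel) + 1L)
        }, numeric(1))
        if (min(bics) < bic0) {
          sel <- c(sel, pool[which.min(bics)])
          changed <- TRUE
        }
      }
    }
    ## backward
    repeat {
      if (!length(sel)) break
      f <- gram_fit(G, g, yy, n, c(1L, sel))
      if (criterion == "pvalue") {
        pv <- f$p[-1L]
        worst <- which.max(pv)
        if (pv[worst] > alpha_out) {
          sel <- sel[-worst]
          changed <- TRUE
        } else break
      } else {
        bic0 <- gram_bic(f$rss, n, length(sel))
        bics <- vapply(seq_along(sel), function(k) {
          fk <- gram_fit(G, g, yy, n, c(1L, sel[-k]))
          if (is.null(fk)) Inf else gram_bic(fk$rss, n, length(sel) - 1L)
        }, numeric(1))
        if (min(bics) < bic0) {
          sel <- sel[-which.min(bics)]
          changed <- TRUE
        } else break
      }
    }
    if (!changed) break
  }
  list(selected = sel, fit = gram_fit(G, g, yy, n, c(1L, sel)))
}

design_gram <- function(data, target, features) {
  miss <- setdiff(c(target, features), names(data))
  if (length(miss)) {
    ppgbp_abort(paste0("columns not in data: ", paste(miss, collapse = ", ")),
                "ppgbp_error_input")
  }
  X <- as.matrix(data[features])
  y <- data[[target]]
  if (anyNA(X) || anyNA(y)) {
    ppgbp_abort("missing values in target or feature columns",
                "ppgbp_error_input")
  }
  Z <- cbind(`(Intercept)` = 1, X)
  list(Z = Z, y = y, G = crossprod(Z), g = drop(crossprod(Z, y)),
       yy = sum(y^2), n = length(y))
}

new_bp_model <- function(intercept, coefficients, target, fit, n,
                         feature_stats, method = "ols") {
  structure(list(intercept = intercept, coefficients = coefficients,
                 selected_features = names(coefficients), target = target,
                 n = n, sigma = sqrt(fit$sigma2), rss = fit$rss,
                 se = fit$se, t = fit$t, p = fit$p, df = fit$df,
                 feature_stats = feature_stats, method = method),
            class = "bp_model")
}

feature_stats_of <- function(data, features) {
  tibble::tibble(
    feature = features,
    mean = vapply(features, function(f) mean(data[[f]]), numeric(1)),
    sd = vapply(features, function(f) stats::sd(data[[f]]), numeric(1)))
}

#' Fit the blood-pressure regression by ordinary least squares
#'
#' Least-squares fit of `target ~ features` with an intercept. The
#' solution is computed from the normal equations via a Cholesky factor
#' of the Gram matrix; a rank-deficient design aborts with the names of
#' the collinear columns.
#'
#' @param data feature table (one row per measurement).
#' @param target name of the target column, mmHg (typically `true_sbp`).
#' @param features character vector of feature column names.
#' @returns a `bp_model` with intercept `u0`, named coefficients `u_i`,
#'   per-term inference, residual scale, and training-set feature
#'   means/SDs for diagnostics.
#' @seealso [stepwise_select()], [predict.bp_model()]
#' @export
#' @examples
#' d <- tibble::tibble(x = c(0, 1, 2), y = c(1, 3, 5))
#' m <- fit_ols(d, "y", "x")
#' coef(m)  # intercept 1, slope 2
fit_ols <- function(data, target, features) {
  dg <- design_gram(data, target, features)
  if (dg$n <= length(features) + 1L) {
    ppgbp_abort("need n > p + 1 observations", "ppgbp_error_input")
  }
  qrz <- qr(dg$Z)
  if (qrz$rank < ncol(dg$Z)) {
    aliased <- colnames(dg$Z)[qrz$pivot[seq.int(qrz$rank + 1L, ncol(dg$Z))]]
    ppgbp_abort(paste0("singular fit; collinear columns: ",
                       paste(aliased, collapse = ", ")),
                "ppgbp_error_singular")
  }
  fit <- gram_fit(dg$G, dg$g, dg$yy, dg$n, seq_len(ncol(dg$Z)))
  beta <- setNames(fit$beta, colnames(dg$Z))
  new_bp_model(intercept = beta[[1L]], coefficients = beta[-1L],
               target = target, fit = fit, n = dg$n,
               feature_stats = feature_stats_of(data, features))
}

#' Stepwise feature selection for the blood-pressure regression
#'
#' Bidirectional stepwise selection over a candidate feature set.
#' In `criterion = "pvalue"` mode (the default) a candidate enters when
#' its partial p-value is below `alpha_in` and a selected term is dropped
#' when its p-value exceeds `alpha_out`; in `"bic"` mode terms are added
#' or removed while the BIC decreases. The procedure is deterministic for
#' a fixed candidate ordering and returns the refitted final model; when
#' nothing passes the entry test the intercept-only model is returned.
#'
#' @param data feature table.
#' @param target target column name, mmHg.
#' @param candidates candidate feature names (default: all 20 features
#'   present in `data`).
#' @param alpha_in,alpha_out entry/exit p-value thresholds (classical
#'   0.05 / 0.10 defaults).
#' @param criterion `"pvalue"` or `"bic"`.
#' @returns a `bp_model`.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(x1 = rnorm(50), x2 = rnorm(50))
#' d$y <- 3 * d$x1
#' stepwise_select(d, "y", c("x1", "x2"))$selected_features  # "x1"
stepwise_select <- function(data, target, candidates = NULL,
                            alpha_in = 0.05, alpha_out = 0.10,
                            criterion = c("pvalue", "bic")) {
  criterion <- match.arg(criterion)
  if (is.null(candidates)) {
    candidates <- intersect(feature_names(), names(data))
  }
  if (!length(candidates)) {
    ## empty candidate set: intercept-only model
    y <- data[[target]]
    fit <- list(beta = mean(y), rss = sum((y - mean(y))^2),
                sigma2 = stats::var(y), se = NA_real_, t = NA_real_,
                p = NA_real_, df = length(y) - 1L)
    return(new_bp_model(mean(y), setNames(numeric(0), character(0)),
                        target, fit, length(y),
                        feature_stats_of(data, character(0)),
                        method = "stepwise"))
  }
  dg <- design_gram(data, target, candidates)
  if (dg$n <= length(candidates) + 1L) {
    ppgbp_abort("need n > |candidates| + 1 observations", "ppgbp_error_input")
  }
  sw <- stepwise_gram(dg$G, dg$g, dg$yy, dg$n,
                      candidates = seq_along(candidates) + 1L,
                      alpha_in = alpha_in, alpha_out = alpha_out,
                      criterion = criterion)
  sel_names <- candidates[sw$selected - 1L]
  beta <- setNames(sw$fit$beta, c("(Intercept)", sel_names))
  new_bp_model(beta[[1L]], beta[-1L], target, sw$fit, dg$n,
               feature_stats_of(data, sel_names), method = "stepwise")
}

#' Predict blood pressure from a fitted model
#'
#' Evaluates `u0 + sum(u_i * x_i)` for each row. All selected features
#' must be present; a missing column aborts with its name.
#'
#' @param object a `bp_model`.
#' @param newdata data frame of feature values.
#' @param ... unused.
#' @returns numeric vector of predictions, mmHg.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  miss <- setdiff(object$selected_features, names(newdata))
  if (length(miss)) {
    ppgbp_abort(paste0("missing feature(s): ", paste(miss, collapse = ", ")),
                "ppgbp_error_missing_feature")
  }
  if (!length(object$selected_features)) {
    return(rep(object$intercept, nrow(newdata)))
  }
  X <- as.matrix(newdata[object$selected_features])
  drop(object$intercept + X %*% object$coefficients)
}

#' @export
coef.bp_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> %s ~ %d feature(s), n = %d, sigma = %.3g mmHg\n",
              x$target, length(x$selected_features), x$n, x$sigma))
  if (length(x$selected_features)) {
    cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a fitted blood-pressure model
#'
#' @param x a `bp_model`.
#' @param ... unused.
#' @returns tibble with one row per term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.bp_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$selected_features),
                 estimate = unname(c(x$intercept, x$coefficients)),
                 std.error = as.numeric(x$se),
                 statistic = as.numeric(x$t),
                 p.value = as.numeric(x$p))
}

#' One-row summary of a fitted blood-pressure model
#'
#' @param x a `bp_model`.
#' @param ... unused.
#' @returns tibble with `n`, `n_features`, `sigma`, `rss`, `df`.
#' @exportS3Method generics::glance
glance.bp_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$selected_features),
                 sigma = x$sigma, rss = x$rss, df = x$df)
}
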