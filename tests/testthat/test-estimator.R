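test_that("OLS reproduces exact lines and degenerate targets", {
  d <- tibble::tibble(x = c(0, 1, 2), y = c(1, 3, 5))
  m <- fit_ols(d, "y", "x")
  expect_equal(unname(coef(m)), c(1, 2), tolerance = 1e-12)

  d2 <- tibble::tibble(x = rnorm(10), y = rep(4, 10))
  m2 <- fit_ols(d2, "y", "x")
  expect_equal(m2$intercept, 4, tolerance = 1e-12)
  expect_equal(unname(m2$coefficients), 0, tolerance = 1e-12)
})

test_that("OLS matches the closed-form normal equations on random designs", {
  withr::with_seed(101, {
    for (rep in 1:100) {
      n <- sample(10:50, 1)
      p <- sample(1:6, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n)
      d <- tibble::as_tibble(as.data.frame(X))
      names(d) <- paste0("x", seq_len(p))
      d$y <- y
      m <- fit_ols(d, "y", paste0("x", seq_len(p)))
      Z <- cbind(1, X)
      beta_ref <- solve(t(Z) %*% Z, t(Z) %*% y)  # independent route
      expect_equal(unname(coef(m)), drop(beta_ref), tolerance = 1e-8)
      ## residuals orthogonal to the design
      res <- y - drop(Z %*% coef(m))
      expect_lt(max(abs(t(Z) %*% res)) / max(abs(t(Z) %*% y)), 1e-8)
    }
  })
})

test_that("rank-deficient designs abort naming the collinear column", {
  d <- tibble::tibble(x1 = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  err <- expect_error(fit_ols(d, "y", c("x1", "x2")),
                      class = "ppgbp_error_singular")
  expect_match(conditionMessage(err), "x2")
})

test_that("OLS recovers the generator's linear map on noiseless cohorts", {
  pop <- generate_population(80, seed = 55, bp_noise_sd = 0,
                             morph_noise_sd = 0)
  ## regress on the raw lobe heights + demographics: exact by construction
  d <- dplyr::rename(pop, h_a = "morph_h_a")
  m <- fit_ols(d, "true_sbp", c("h_a", "age", "sex", "weight"))
  pred <- predict(m, d)
  expect_equal(pred, pop$true_sbp, tolerance = 1e-6)
})

test_that("stepwise selects the true predictor and agrees with best-subset BIC", {
  for (seed in 1:20) {
    withr::with_seed(200 + seed, {
      n <- 60
      d <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(n * 5), n)),
                                      paste0("x", 1:5)))
      d$y <- 3 * d$x1 + rnorm(n, 0, 0.5)
    })
    m <- stepwise_select(d, "y", paste0("x", 1:5), criterion = "bic")
    expect_identical(sort(m$selected_features),
                     best_subset_bic(d, "y", paste0("x", 1:5)))
  }
  ## pure signal: p-value mode finds exactly x1
  withr::with_seed(77, {
    d <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(300), 100)),
                                    paste0("x", 1:3)))
    d$y <- 3 * d$x1
  })
  m <- stepwise_select(d, "y", paste0("x", 1:3))
  expect_identical(m$selected_features, "x1")
  expect_equal(unname(m$coefficients), 3, tolerance = 1e-10)
})

test_that("stepwise under the null mostly returns the intercept-only model", {
  hits <- 0L
  for (seed in 1:100) {
    withr::with_seed(3000 + seed, {
      d <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(1000), 200)),
                                      paste0("x", 1:5)))
      d$y <- rnorm(200)
    })
    m <- stepwise_select(d, "y", paste0("x", 1:5), alpha_in = 0.05)
    if (!length(m$selected_features)) hits <- hits + 1L
  }
  expect_gte(hits, 70L)
})

test_that("empty candidate sets give the intercept-only model", {
  d <- tibble::tibble(y = c(1, 2, 3, 4))
  m <- stepwise_select(d, "y", character(0))
  expect_identical(m$selected_features, character(0))
  expect_equal(m$intercept, 2.5)
  expect_equal(predict(m, d), rep(2.5, 4))
})

test_that("prediction follows the regression equation exactly", {
  m <- structure(list(intercept = 80, coefficients = c(pr = 0.2),
                      selected_features = "pr", target = "true_sbp"),
                 class = "bp_model")
  expect_equal(predict(m, tibble::tibble(pr = 60)), 92)
  expect_error(predict(m, tibble::tibble(a = 1)),
               class = "ppgbp_error_missing_feature")
  ## refit on the training set: mean of predictions equals mean of target
  withr::with_seed(5, {
    d <- tibble::tibble(x = rnorm(30), y = rnorm(30, 120, 10))
  })
  mf <- fit_ols(d, "y", "x")
  expect_equal(mean(predict(mf, d)), mean(d$y), tolerance = 1e-9)
})

test_that("stepwise refit on the selected set reproduces its coefficients", {
  pop <- generate_population(150, seed = 60, bp_noise_sd = 5)
  d <- dplyr::rename(pop, h_a = "morph_h_a", h_b = "morph_h_b")
  m <- stepwise_select(d, "true_sbp", c("h_a", "h_b", "age", "sex", "weight"))
  refit <- fit_ols(d, "true_sbp", m$selected_features)
  expect_equal(coef(m), coef(refit), tolerance = 1e-10)
  expect_true(all(m$selected_features %in% c("h_a", "h_b", "age", "sex",
                                             "weight")))
})

test_that("the PTT baseline fits deviations from the first reading", {
  ptt <- c(300, 299, 298, 297)
  bp <- c(120, 122, 124, 126)  # bpv = -2 * pttv
  fit <- fit_ptt_baseline(ptt, bp)
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$reference_bp, 120)
  expect_equal(fit$reference_ptt, 300)
  expect_equal(predict(fit, 295), 120 + -2 * -5)
  ## the reference reading's deviations are zero by construction
  expect_equal(predict(fit, fit$reference_ptt), fit$reference_bp)
  expect_error(fit_ptt_baseline(rep(300, 5), 1:5),
               class = "ppgbp_error_degenerate_baseline")
  expect_error(fit_ptt_baseline(1:2, 1:2), class = "ppgbp_error_input")
})

test_that("an uninformative PTT gives near-zero skill at n = 27", {
  withr::with_seed(88, {
    bp <- rnorm(27, 120, 10)
    ptt <- rnorm(27, 300, 10)  # unrelated to bp
  })
  fit <- fit_ptt_baseline(ptt, bp)
  ev <- error_metrics(bp, predict(fit, ptt))
  expect_lt(abs(ev$r), 0.3)
})

test_that("LOOCV honours its protocol on exact and tiny data", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5), true_sbp = 10 + 2 * c(1, 2, 3, 4, 5))
  ev <- loocv(d, method = "ols", candidates = "x")
  expect_equal(ev$r, 1.0, tolerance = 1e-8)
  expect_equal(ev$mean_error, 0, tolerance = 1e-8)
  expect_equal(ev$sd_error, 0, tolerance = 1e-8)
  d3 <- tibble::tibble(x = c(0, 1, 2), true_sbp = c(1, 3, 5.5))
  ev3 <- loocv(d3, method = "ols", candidates = "x")
  expect_identical(ev3$n, 3L)  # three folds, each a 2-point fit
  ## fold 3 prediction comes from the line through the first two points
  expect_equal(ev3$predictions$estimated[3], 1 + 2 * 2, tolerance = 1e-9)
  expect_error(loocv(d3[1:2, ], method = "ols", candidates = "x"),
               class = "ppgbp_error_input")
})

test_that("error metrics compute the reported triplet", {
  ev <- error_metrics(c(100, 110, 120), c(102, 112, 118))
  expect_equal(ev$mean_error, 2 / 3, tolerance = 1e-12)
  expect_equal(ev$sd_error, sqrt(16 / 3), tolerance = 1e-12)
  g <- glance(ev)
  expect_named(g, c("r", "mean_error", "sd_error", "n"))

  same <- error_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$r, 1)
  expect_equal(same$mean_error, 0)
  expect_equal(same$sd_error, 0)

  shift <- error_metrics(c(1, 2, 3), c(6, 7, 8))
  expect_equal(shift$r, 1)
  expect_equal(shift$mean_error, 5)
  expect_equal(shift$sd_error, 0)

  flat <- error_metrics(c(1, 1, 1), c(1, 2, 3))
  expect_true(flat$r_undefined)

  ## per-subject breakdown
  ev2 <- error_metrics(c(100, 100, 120, 120), c(101, 103, 119, 121),
                       subject_id = c("s1", "s1", "s2", "s2"))
  td <- tidy(ev2)
  expect_equal(td$mean_error[td$subject_id == "s1"], 2)
})

test_that("the static ablation removes exactly the questionnaire covariates", {
  pop <- generate_population(120, seed = 70, bp_noise_sd = 5)
  d <- dplyr::rename(pop, a = "morph_h_a", b = "morph_h_b", e = "morph_h_e")
  ab <- ablation_static_features(d, candidates = c("a", "b", "e", "height",
                                                   "weight", "age", "sex"))
  expect_identical(ab$ablated_candidates, c("a", "b", "e"))
  expect_s3_class(ab$full, "bp_eval")
  expect_s3_class(ab$ablated, "bp_eval")
})

test_that("ablation is a no-op when covariates carry no BP information", {
  pop <- generate_population(
    600, seed = 72, bp_noise_sd = 5,
    base_effects = c(intercept = 120, age = 0, sex = 0, weight = 0))
  d <- dplyr::rename(pop, a = "morph_h_a", b = "morph_h_b", c = "morph_h_c",
                     d = "morph_h_d", e = "morph_h_e")
  ab <- ablation_static_features(
    d, candidates = c("a", "b", "c", "d", "e", "height", "weight", "age",
                      "sex"))
  expect_lt(abs(ab$full$r - ab$ablated$r), 0.05)
})

test_that("model JSON round-trips through the writers", {
  pop <- generate_population(60, seed = 71, bp_noise_sd = 5)
  d <- dplyr::rename(pop, a = "morph_h_a")
  m <- fit_ols(d, "true_sbp", c("a", "age"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_identical(m2$target, "true_sbp")
  expect_equal(predict(m2, d), predict(m, d), tolerance = 1e-12)
})
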