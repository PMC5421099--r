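test_that("fiducials on a noiseless beat match the generator sidecar", {
  for (seed in c(31, 32, 33)) {
    fix <- quick_recording(seed = seed, duration = 10)
    ch <- condition_chain(fix$signal)
    fid <- detect_fiducials(ch$apg, ch$beats)
    m <- match_beats(fix$truth, ch$beats)
    expect_false(anyNA(m))
    fid <- fid[m, ]
    ok <- as.matrix(fid[paste0("ok_", wave_names)])
    expect_true(all(ok))
    for (w in wave_names) {
      expect_lt(max(abs(fid[[paste0("t_", w)]] - fix$truth[[paste0("t_", w)]])),
                0.010)
      expect_lt(max(abs(fid[[paste0("h_", w)]] / fix$truth[[paste0("h_", w)]] - 1)),
                0.05)
    }
  }
})

test_that("an all-zero beat yields no fiducials", {
  fs <- 100
  zero <- ppg_signal(rep(0, 400), fs)
  apg <- second_derivative(zero)
  beats <- tibble::tibble(beat = 1L, onset = 50L, onset_time = 0.5,
                          end = 150L, period = 1.0)
  fid <- detect_fiducials(apg, beats)
  expect_false(any(unlist(fid[paste0("ok_", wave_names)])))
})

test_that("suppressed c/d lobes are flagged invalid, e is still found", {
  subj <- generate_population(1, seed = 34)
  subj$morph_h_c <- 0
  subj$morph_h_d <- 0
  rec <- synthesize_ppg(subj, duration = 10, noise_sd = 0)
  ch <- condition_chain(rec$signal)
  fid <- detect_fiducials(ch$apg, ch$beats)
  expect_true(all(fid$ok_a) && all(fid$ok_b) && all(fid$ok_e))
  expect_false(any(fid$ok_c) || any(fid$ok_d))
  ## generator truth agrees
  expect_true(all(is.na(rec$truth$t_c)) && all(is.na(rec$truth$t_d)))
  expect_false(anyNA(rec$truth$t_e))
})

test_that("APG index follows its formula and is scale invariant", {
  expect_equal(apg_index(1, -0.8, 0.1, -0.3), 0.6)
  expect_equal(apg_index(2, 0, 0, 0), 0)
  k <- 13.7
  expect_equal(apg_index(k * 1, k * -0.8, k * 0.1, k * -0.3), 0.6)
  expect_error(apg_index(0, -1, 1, -1), class = "ppgbp_error_degenerate_beat")
})

test_that("window aggregation is the median over fully valid beats", {
  mk_row <- function(a) {
    out <- list(beat = 1L, onset_time = 0, period = 1)
    for (w in wave_names) {
      out[[paste0("ok_", w)]] <- TRUE
      out[[paste0("t_", w)]] <- 0.1
      out[[paste0("h_", w)]] <- if (w == "a") a else 1
    }
    tibble::as_tibble(out)
  }
  subj <- tibble::tibble(height = 1.7, weight = 70, age = 40, sex = 1L)
  fid3 <- dplyr::bind_rows(mk_row(1.0), mk_row(1.2), mk_row(5.0))
  fv <- compute_features(fid3, pr = 60, subject = subj)
  expect_equal(fv$a, 1.2)
  fv1 <- compute_features(mk_row(2.5), pr = 72, subject = subj)
  expect_equal(fv1$a, 2.5)
  expect_equal(fv1$pr, 72)
  expect_identical(names(fv), feature_names())
  ## no fully valid beat -> classed signal
  bad <- mk_row(1.0)
  bad$ok_c <- FALSE
  expect_error(compute_features(bad, 60, subj),
               class = "ppgbp_error_no_features")
})

test_that("noiseless window features reproduce the ground-truth ratios", {
  fix <- quick_recording(seed = 35, duration = 60)
  fv <- extract_features(fix$signal, fix$subject)
  expect_equal(fv$b_a, fix$truth$h_b[1] / fix$truth$h_a[1], tolerance = 0.05)
  expect_equal(fv$pr, 60 / fix$subject$heart_period, tolerance = 0.02)
})

test_that("ratio and time features ignore amplitude scaling and delay", {
  fix <- quick_recording(seed = 36, duration = 10)
  fv <- extract_features(fix$signal, fix$subject)
  scaled <- fix$signal
  scaled$amplitude <- scaled$amplitude * 3.2
  fvs <- extract_features(scaled, fix$subject)
  for (col in c("b_a", "c_a", "d_a", "e_a", "apg_index",
                paste0("T_", wave_names))) {
    expect_equal(fvs[[col]], fv[[col]], tolerance = 1e-8)
  }
  expect_equal(fvs$a, 3.2 * fv$a, tolerance = 1e-8)
  ## delay the recording by prepending half a period of the periodic signal
  subj <- fix$subject
  rec_long <- synthesize_ppg(subj, duration = 12, noise_sd = 0)
  shift <- round(0.5 * subj$heart_period * 100)
  delayed <- ppg_signal(rec_long$signal$amplitude[(shift + 1):(shift + 1000)],
                        100)
  fvd <- extract_features(delayed, subj)
  ## filter edge effects limit agreement to ~0.1% / ~0.5 ms, far below
  ## the waves' physiological variation
  for (col in paste0("T_", wave_names)) {
    expect_lt(abs(fvd[[col]] - fv[[col]]), 1e-3)
  }
  for (col in c("b_a", "apg_index")) {
    expect_equal(fvd[[col]], fv[[col]], tolerance = 2e-3)
  }
})

test_that("detected wave times are chronologically ordered whenever valid", {
  for (seed in 41:48) {
    fix <- quick_recording(seed = seed, duration = 10, noise_sd = 0.005)
    ch <- condition_chain(fix$signal)
    fid <- detect_fiducials(ch$apg, ch$beats)
    full <- rowSums(!as.matrix(fid[paste0("ok_", wave_names)])) == 0
    tt <- as.matrix(fid[full, paste0("t_", wave_names)])
    if (nrow(tt)) expect_true(all(tt[, -1] > tt[, -5]))
  }
})
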