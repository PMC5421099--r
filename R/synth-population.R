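## Synthetic subject population
##
## The generator encodes the working model of the estimator: demographics
## set a subject's basal systolic pressure, a hemodynamic deviation moves
## the pressure around that basis, and the APG morphology responds
## linearly to the deviation (a-wave up, b- and e-waves down as pressure
## rises) and to age. The cuff reading used as the regression target is
## the hemodynamic pressure plus independent measurement noise, which is
## the irreducible error floor of any feature-based model.

## per-mmHg lobe-height slopes (relative change per mmHg of deviation)
MORPH_BP_SLOPE <- c(a = 0.020, b = 0.015, c = -0.010, d = 0.010, e = -0.015)
## per-unit-age-score slopes (age score = (age - 50)/30, clamped to [-1, 1])
MORPH_AGE_SLOPE <- c(a = -0.05, b = 0.15, c = -0.10, d = 0.05, e = -0.10)
## age shift of the c-lobe centre (fraction of the heart period per age score)
MORPH_AGE_MU_C <- 0.015

## basal SBP model (mmHg): intercept + effects of age, sex, weight
SBP_BASE_DEFAULT <- c(intercept = 100, age = 0.5, sex = -8, weight = 0.12)

age_score <- function(age) pmax(pmin((age - 50) / 30, 1), -1)

#' Generate a synthetic subject population
#'
#' Draws demographics (height, weight, age, sex), basal and deviation
#' components of systolic pressure, a heart period, and the APG beat
#' morphology of each subject. The morphology is an invertible linear
#' function of the pressure deviation and age plus independent relative
#' noise, so a linear feature-to-SBP model is recoverable by design:
#' the a-lobe grows and the b- and e-lobes shrink as pressure rises.
#'
#' @param n number of subjects (>= 1).
#' @param seed integer seed; identical seeds give identical populations.
#' @param age_range,height_mean,weight_bmi_mean demographic settings:
#'   uniform age range in years, sex-specific mean heights in metres
#'   (`c(male, female)`), and mean body-mass index.
#' @param base_effects named numeric `(intercept, age, sex, weight)` of the
#'   basal-SBP model in mmHg (weight effect per kg about 75 kg).
#' @param bp_spread_sd SD of the hemodynamic SBP deviation around the
#'   basis, mmHg (truncated at 2 SD).
#' @param bp_noise_sd SD of the cuff measurement noise added on top of the
#'   hemodynamic pressure, mmHg; this is irreducible for the estimator.
#' @param morph_noise_sd relative SD of the independent lobe-height noise.
#' @param heart_period_mean,heart_period_sd heart period distribution, s.
#' @returns a tibble with one row per subject: `subject_id`, `height`,
#'   `weight`, `age`, `sex` (male 0, female 1), `heart_period`,
#'   `sbp_base`, `sbp_dev`, `sbp_model` (hemodynamic SBP), `true_sbp`
#'   (cuff reading, the regression target), `true_dbp`, and morphology
#'   columns `morph_h_a` .. `morph_h_e`, `morph_mu_a` .. `morph_mu_e`
#'   (centre fractions) and `morph_sig_a` .. `morph_sig_e` (widths, s).
#' @export
#' @examples
#' pop <- generate_population(5, seed = 7)
#' pop$true_sbp
generate_population <- function(n, seed = NULL,
                                age_range = c(20, 80),
                                height_mean = c(1.75, 1.62),
                                weight_bmi_mean = 24,
                                base_effects = SBP_BASE_DEFAULT,
                                bp_spread_sd = 10,
                                bp_noise_sd = 8,
                                morph_noise_sd = 0.05,
                                heart_period_mean = 0.85,
                                heart_period_sd = 0.08) {
  if (!(is.numeric(n) && length(n) == 1L && n >= 1)) {
    ppgbp_abort("`n` must be a single count >= 1", "ppgbp_error_config")
  }
  if (diff(age_range) <= 0 || bp_spread_sd < 0 || bp_noise_sd < 0 ||
      morph_noise_sd < 0 || heart_period_sd < 0) {
    ppgbp_abort("degenerate demographic or noise configuration",
                "ppgbp_error_config")
  }
  n <- as.integer(n)
  with_seed_if(seed, {
    age <- round(runif(n, age_range[1], age_range[2]))
    sex <- stats::rbinom(n, 1L, 0.5)
    height <- rnorm_trunc(n, ifelse(sex == 0, height_mean[1], height_mean[2]),
                          0.06, lim = 3)
    height <- pmax(pmin(height, 2.05), 1.45)
    bmi <- rnorm_trunc(n, weight_bmi_mean, 3, lim = 3)
    weight <- pmax(pmin(bmi * height^2, 135), 40)
    heart_period <- if (heart_period_sd > 0) {
      pmax(pmin(rnorm_trunc(n, heart_period_mean, heart_period_sd, lim = 2.5),
                1.10), 0.65)
    } else rep(heart_period_mean, n)

    sbp_base <- base_effects[["intercept"]] + base_effects[["age"]] * age +
      base_effects[["sex"]] * sex + base_effects[["weight"]] * (weight - 75)
    sbp_dev <- if (bp_spread_sd > 0) rnorm_trunc(n, 0, bp_spread_sd, lim = 2)
               else numeric(n)
    sbp_model <- sbp_base + sbp_dev
    meas <- if (bp_noise_sd > 0) rnorm_trunc(n, 0, bp_noise_sd, lim = 3)
            else numeric(n)
    true_sbp <- pmax(pmin(sbp_model + meas, 200), 80)
    true_dbp <- 0.55 * sbp_model + 8 +
      if (bp_noise_sd > 0) rnorm_trunc(n, 0, 3, lim = 3) else 0
    true_dbp <- pmin(true_dbp, true_sbp - 10)

    ws <- age_score(age)
    eta <- function() {
      if (morph_noise_sd > 0) rnorm_trunc(n, 0, morph_noise_sd, lim = 3)
      else numeric(n)
    }
    morph <- list()
    for (wv in WAVE_NAMES) {
      gain <- (1 + MORPH_BP_SLOPE[[wv]] * sbp_dev +
                 MORPH_AGE_SLOPE[[wv]] * ws) * (1 + eta())
      morph[[paste0("morph_h_", wv)]] <- MORPH_REF_HEIGHT[[wv]] * gain
      mu <- MORPH_REF_MU[[wv]] +
        if (wv == "c") MORPH_AGE_MU_C * ws else 0
      morph[[paste0("morph_mu_", wv)]] <- rep(mu, length.out = n)
      morph[[paste0("morph_sig_", wv)]] <- rep(MORPH_REF_SIGMA[[wv]], n)
    }

    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      height = height, weight = weight, age = age, sex = sex,
      heart_period = heart_period,
      sbp_base = sbp_base, sbp_dev = sbp_dev, sbp_model = sbp_model,
      true_sbp = true_sbp, true_dbp = true_dbp,
      !!!morph)
  })
}

#' Generator-side linear predictor of systolic pressure
#'
#' Inverts the documented morphology map: recovers the pressure deviation
#' from the generated a-lobe height and the subject's age, and adds the
#' basal-SBP model. With the morphology and measurement noise set to
#' zero this reproduces `true_sbp` exactly; it is the closed-form oracle
#' that the waveform-level pipeline is expected to approximate.
#'
#' @param population tibble from [generate_population()].
#' @param base_effects the basal-SBP effects used at generation time.
#' @returns numeric vector of predicted SBP, mmHg.
#' @export
sbp_linear_predictor <- function(population, base_effects = SBP_BASE_DEFAULT) {
  ws <- age_score(population$age)
  dev_hat <- (population$morph_h_a / MORPH_REF_HEIGHT[["a"]] - 1 -
                MORPH_AGE_SLOPE[["a"]] * ws) / MORPH_BP_SLOPE[["a"]]
  base <- base_effects[["intercept"]] + base_effects[["age"]] * population$age +
    base_effects[["sex"]] * population$sex +
    base_effects[["weight"]] * (population$weight - 75)
  base + dev_hat
}
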