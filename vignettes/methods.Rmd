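---
title: "Cuffless systolic blood pressure from wrist PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless systolic blood pressure from wrist PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous blood-pressure monitoring with a cuff is impractical: the
inflation is uncomfortable, wakes sleepers, and itself perturbs the
pressure being measured. A single wrist photoplethysmograph (PPG) — a
green-LED optical sensor sampling blood-volume change at 100 Hz — can be
worn all day. `ppgbp` implements the pulse-wave-analysis route to
cuffless estimation: the *shape* of each pulse carries information about
vascular tone and driving pressure, and a regression on shape features
plus basic questionnaire covariates predicts systolic pressure (SBP)
without per-subject calibration. The conventional alternative,
pulse-transit-time (PTT) regression, needs a second sensor (ECG) and a
cuff calibration, and is implemented here as the comparison baseline.

## Signal model

The **acceleration plethysmogram (APG)** is the second time derivative
of the PPG. Within one beat its alternating extrema are named, in
chronological order, the *a* (maximum), *b* (minimum), *c*, *d* and *e*
waves: a and b reflect the systolic driving wave, c and d the reflected
wave, e the diastolic component after aortic-valve closure. Twenty
features form the estimation vector:

| group | features | units |
|---|---|---|
| wave heights | a, b, c, d, e | a.u./s² |
| latencies from the APG rise | T_a … T_e | s |
| height ratios | b/a, c/a, d/a, e/a | – |
| composite | APG index = (c + d − b)/a | – |
| dynamics | PR (pulse rate, trailing minute) | bpm |
| questionnaire | height (m), weight (kg), age (yr), sex (male 0 / female 1) | – |

The estimator is the linear model

$$y = u_0 + u_1 x_1 + \dots + u_p x_p,$$

with $y$ the systolic pressure and the subset $x_1 \dots x_p$ chosen by
bidirectional stepwise selection. In the default mode a candidate enters
when its partial $p$-value is below $\alpha_{in} = 0.05$ and a term is
dropped when its $p$-value exceeds $\alpha_{out} = 0.10$ (the classical
thresholds; the method's source names stepwise selection but not its
settings). A greedy BIC mode is provided as well and is the one
cross-checked against exhaustive best-subset search in the tests. Errors
are reported as **estimated − measured** throughout, as the triplet
(Pearson r, mean error, SD of errors with the $n-1$ denominator).

## The synthetic generator — what it emulates

No public recordings accompany the method, so the package ships a
generator whose *defaults are the study conditions* for every test and
for `scripts/acceptance.R`:

* **Demographics**: age uniform on 20–80 y, sex balanced, sex-specific
  heights (1.75/1.62 ± 0.06 m), BMI 24 ± 3.
* **Basal SBP**: $100 + 0.5\,\mathrm{age} - 8\,\mathrm{sex} +
  0.12(\mathrm{weight}-75)$ mmHg — the magnitudes a clinician would call
  unremarkable (≈ +5 mmHg per decade, men a few mmHg above women).
* **Hemodynamic deviation**: N(0, 10 mmHg), truncated at ±2 SD, moves a
  subject off their basis; it is what the waveform actually encodes.
* **Cuff reading** (`true_sbp`, the regression target): hemodynamic SBP
  plus N(0, `bp_noise_sd`) measurement noise, default 8 mmHg. This noise
  never reaches the waveform and is therefore the irreducible error
  floor of any feature-based estimator — the quantity the
  cohort-recovery checks band around.
* **Morphology**: the five APG lobe heights respond linearly to the
  deviation (a: +2%/mmHg; b: −1.5%/mmHg of its magnitude; e: −1.5%/mmHg;
  c, d smaller) and to an age score (b/a grows, c/a and e/a shrink with
  age, matching the pulse-wave-ageing literature), times independent
  relative noise (default SD 5%). The map is linear and invertible, so
  with all noise off a linear model recovers SBP exactly — the
  `r ≥ 0.999` ceiling the tests assert.

**The beat waveform** is designed in the APG domain: five Gaussian lobes
with alternating signs at fixed fractions of the heart period
(0.10, 0.20, 0.32, 0.42, 0.72; the c-centre shifts slightly with age)
plus a slow sin² pulse envelope, projected on 16 Fourier harmonics; the
PPG is the exact double antiderivative of that series. Designing in the
PPG domain instead (one bump per wave) does not work: a Gaussian bump's
second derivative carries ±45% side lobes that destroy the a–e
structure. Because a periodic signal's second derivative has zero mean,
the DC of the lobe sum is dropped, which offsets all wave heights by a
common, morphology-linear constant — harmless to the linear recovery,
but the reason c/d/e *net* heights can sit closer to zero than their
lobe amplitudes. Ground truth (beat onset, a–e latencies and heights) is
read off the analytic APG on a 0.2 ms grid with the same
prominence-and-ordering rule as the detector; it is exact for the
noiseless waveform, not a re-run of the pipeline.

What the generator deliberately does **not** model: motion artifacts,
baseline wander, beat-to-beat morphology variation within a recording,
arrhythmia, sensor saturation, and any nonlinear BP–waveform coupling.
Passing tests therefore demonstrate that the pipeline is correct and
well-conditioned under the stated model, not that it attains any
particular accuracy on real wrist recordings.

## Processing pipeline and numerical choices

1. **Band-pass** 0.2–20 Hz, 4th-order Butterworth applied
   forward-backward (zero phase), after explicit mean removal and with
   odd-reflection padding (2 s) so edge transients cannot masquerade as
   beats. The band was chosen by measurement against the analytic
   truth: a high-pass at 0.4–0.5 Hz already erodes the pulse fundamental
   (0.9–1.5 Hz) enough to bias wave heights by several percent, and a
   10 Hz low-pass clips the APG lobes outright (they carry energy to
   ~15 Hz); 0.2–20 Hz keeps worst-case noiseless height errors under 3%.
2. **Differentiation**: Savitzky–Golay second derivative, local quartic
   over a 7-sample window at 100 Hz. A local quadratic of the same width
   attenuates the narrow lobes by 8–17%; the quartic is measured at
   < 3%. The half-window edge samples are flagged invalid, not
   extrapolated.
3. **Beat segmentation**: a-wave candidates are prominent APG maxima
   (≥ half the 95th-percentile peak height, ≥ 300 ms apart); each onset
   is the PPG minimum (pulse foot) within 250 ms before its a-wave,
   refined by parabolic interpolation; inter-onset intervals outside
   0.3–2.0 s are dropped. This interval filter is the package's minimal
   stand-in for the unspecified "troubled measurement" exclusion of the
   original protocol; stricter quality rules stay configurable.
4. **Fiducial detection**: within (onset, onset + 0.75·period], local
   extrema must clear a topographic prominence of 2% of the beat's APG
   peak-to-peak range (suppresses noise ripples). a = highest accepted
   maximum; b = first minimum after a; c, d = next maximum/minimum
   within 0.6·period; e = the following maximum out to 0.75·period. A
   maximum beyond 0.6·period is accepted as e even when c/d are absent,
   which is how a merged dicrotic structure degrades gracefully: c and d
   are flagged invalid rather than recovered from inflections. Times and
   heights are refined by parabolic interpolation (sub-sample, sub-1%).
5. **Aggregation**: one feature vector per measurement window, medians
   over the fully valid beats (robust to occasional missed detections);
   ratios and the APG index are computed from the aggregated heights.
   Pulse rate is the interval-based count over the trailing 60 s.
6. **Fitting**: all least squares is solved from the Gram matrix by
   Cholesky (cross-checked against the closed-form normal equations to
   1e−8); leave-one-out folds reuse the full Gram matrix via rank-one
   downdates, so LOOCV with per-fold re-selection over 20 candidates at
   n = 600 costs seconds. Rank-deficient designs abort naming the
   collinear columns; ties in stepwise entry resolve to the first
   candidate in the given order, making selection deterministic.

## Evaluation protocols

`loocv()` predicts each measurement from a model fitted on the rest
(selection re-run inside every fold — selection is part of the
estimator), and supports three fitters: the stepwise pulse-wave model,
a fixed-feature OLS, and the PTT baseline (simple regression of pressure
on transit time; `fit_ptt_baseline()` implements the classical deviation
form around the first reading). `ablation_static_features()` re-runs
LOOCV without height, weight, age and sex to quantify how much of the
estimate rests on personal information: under the generator's defaults
the full set outperforms the ablated set because the covariates locate a
subject's basal pressure while the waveform carries the deviation —
mirroring, qualitatively, the interpretation the method's source gives.

Problem sizes used by the tests and the acceptance script — 600-subject
cohorts at 10 s per recording for cohort recovery, 50 noiseless
recordings for the detector oracle, 25–50 30-subject replicates for the
stepwise-vs-PTT ordering, 100 seeds × 4 patterns for dipping closure —
were chosen so each check has clear statistical margin while the whole
suite stays desk-scale.

## 24-hour variability analytics

Daytime is the half-open local-clock window [06:00, 22:00), nighttime
its complement; a reading stamped exactly 22:00 is nocturnal. The
nocturnal decline is $100(\bar{S}_{day}-\bar{S}_{night})/\bar{S}_{day}$
on the SBP means, and the four patterns partition the axis: decline < 0
riser, [0, 10) nondipper, [10, 20) dipper, ≥ 20 extreme-dipper. The
verbatim clinical definitions overlap at exactly 10% ("10% or less"
nondipper vs "10% or more" dipper) and at 20%; the boundaries are
assigned to the stronger-dipping class, the standard convention. The
label is driven by SBP; the DBP decline is computed and reported but not
used. Daily summaries (mean SBP/DBP, max SBP, min DBP), Monday-first
weekly extremes, and half-open-bin histograms complete the analytics;
BMI and a configurable step-to-kilocalorie factor are exposed as the two
display helpers.

## Known limitations

* The synthetic cohort is stationary and single-beat-template per
  subject; the generator's linearity is what makes exact recovery
  provable, and real waveforms will not be this kind.
* The p-value stepwise mode inherits the usual caveats of stepwise
  inference (post-selection p-values are optimistic); the BIC mode and
  the exhaustive-search cross-check exist for that reason.
* The detector assumes an upright pulse (positive a-wave); inverted or
  heavily clipped signals yield empty beat lists rather than recoveries.
* `second_derivative()` is tuned for 100 Hz; at materially different
  rates the window width should be rescaled by the user.
* The store-and-forward outbox retries every pending record on each
  drain; a record that fails while later ones succeed is re-delivered
  after them, so downstream consumers must key on record identity, not
  arrival order, across drain passes.
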