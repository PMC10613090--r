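---
title: "Correcting gestational-age measurement error by regression calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting gestational-age measurement error by regression calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Let `T` be the unknown true gestational age (weeks) of a pregnancy, and
let up to three error-prone assessments be observed:

* ultrasound, `Q_US = T + δ_US`, assumed unbiased with independent random
  error — the gold standard;
* fundal height, `Q_FH = T + b_FH + δ_FH`;
* last menstrual period, `Q_LMP = T + b_LMP + δ_LMP`;

with mutually independent zero-mean errors, independent of `T` (the
classical error model). A binary outcome (neonatal death, low birth
weight) follows a logistic model in `T` with log odds ratio `λ_T` per
week. Regressing the outcome on a raw `Q` instead of `T` attenuates the
slope by approximately the reliability ratio
`σ_T²/(σ_T² + σ_δ²)` (`theoretical_attenuation()`), so the naive
estimate `λ_Q` understates the association.

**Regression calibration** replaces `Q` by the fitted conditional mean
`E(T | Q, Z)`: on the sub-cohort with ultrasound, `Q_US` is regressed by
OLS on the error-prone measurement(s) and a vector `Z` of covariates
assumed error-free (maternal age, education, first pregnancy, trimester
at enrolment, malaria, syphilis, HIV, haemoglobin at enrolment and
delivery, MUAC, infant sex, and birth weight). The fitted mean is then
evaluated for every record with complete predictors, with or without
ultrasound, and used as the exposure in the outcome regression. Because
`T = E(T|Q,Z) + e` with `e` independent of the predictors, the
calibrated exposure yields an approximately unbiased `λ_T` for rare
outcomes. Birth weight is removed from `Z` when the outcome is low
birth weight, whose definition (< 2,500 g) involves birth weight itself.

Key assumptions: non-differential error (outcome depends on `T` only),
an unbiased gold standard with independent error, and a correctly
specified linear calibration model. No error-in-gold-standard
adjustment, SIMEX, or Bayesian error model is attempted.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `mu_T`, `sigma_T` | 38.7, 2.15 | weeks | cohort mean/SD of GA at delivery in the emulated setting |
| `T_bounds` | (30, 44) | weeks | plausible gestations; rejection-sampled truncation (the ultrasound trimming window is 28–44) |
| `sigma_US` | 0.8 | weeks | most precise method |
| `bias_FH`, `sigma_FH` | +0.25, 1.2 | weeks | FH slightly overestimates; intermediate precision |
| `bias_LMP`, `sigma_LMP` | 0, 3.0 | weeks | recall error dominates; least precise |
| `p_avail_US/FH/LMP` | 0.428 / 0.917 / 0.989 | — | observed availability pattern |
| `lambda_T_death` | −0.2 | log OR/week | true mortality association |
| `intercept_death` | logit(0.011) | — | ~1.1% neonatal mortality at the mean GA |
| `bw_intercept`, `bw_slope`, `bw_sigma` | 3209, 150, 450 | g, g/week, g | birth weight linear in GA |
| trimming | 0.5 / 99.5 | percentiles | excludes implausible ultrasound values (nearest-rank, inclusive) |
| LOA multiplier `k` | 2 | — | limits of agreement as mean ± 2·SD; `k = 1.96` by flag |
| preterm cutoff | 37 | weeks | strict `<` |
| bootstrap | B = 1000, m = 1500, with replacement | — | SD of replicate log ORs is the SE; percentile CI default |

The within-method error SDs are not observable quantities of the
emulated study; they were reverse-engineered once from the printed
validity correlations (`ρ(FH, US) ≈ 0.82`, `ρ(LMP, US) ≈ 0.48–0.57`) via
the closed form `ρ = σ_T²/√((σ_T²+σ_FH²)(σ_T²+σ_US²))`, and are defaults,
not constants.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws `T` truncated-normal, adds independent normal
errors per method, draws covariates independently of `T` from plausible
marginals (birth weight is the one `T`-dependent covariate), and draws
the death outcome from the logistic model in `T`. Low birth weight is
deterministic: `birth_weight < 2500`. `apply_availability()` masks each
measurement by an independent Bernoulli indicator.

It deliberately does **not** emulate: correlated covariates (real
haemoglobin measures, age and parity are dependent), covariate-dependent
measurement error (FH error grows with maternal size), non-normal or
heteroscedastic errors, ultrasound biometry formulas, twins, or
informative missingness. A green test therefore establishes that the
*methods* behave as the classical-error theory predicts in the stated
world — not that the defaults reproduce any particular cohort's tables.
One visible consequence: with the stated birth-weight model
(SD ≈ √(150²·2.15² + 450²) ≈ 554 g), the implied low-birth-weight
prevalence is ≈ 10%, higher than the ~5.3% typical of such cohorts; the
parameters are kept as stated rather than re-tuned, and no acceptance
quantity depends on the LBW prevalence.

## Numerical choices

* **Percentile trimming** uses the nearest-rank rule
  (rank `⌈p/100·n⌉`, floored at 1) with *inclusive* exclusion (values
  equal to a threshold are dropped), and reports the realized
  thresholds. Trimming affects the calibration fit only; trimmed records
  still receive predictions.
* **OLS** is solved by QR; a rank-deficient design is rejected naming
  the collinear columns. Inside bootstrap replicates only,
  zero-variance design columns (e.g. a rare binary covariate that
  resampled to all zeros) are dropped instead — their effect is
  unidentifiable and absorbed into the intercept — because rejecting
  such replicates wholesale would discard 10–20% of resamples in
  small-validation settings and bias the SE. Factor covariates use
  reference-first indicator coding; any full-rank coding gives identical
  predictions. Categories unseen at fit time predict `NA`.
* **Logistic fits** run IRLS and then polish the MLE with explicit
  Newton steps (tolerance 1e−12) so the estimate and its
  observed-information SE match closed forms on saturated 2×2 layouts to
  machine precision. Complete separation is detected exactly for the
  univariable case (disjoint exposure ranges of events and non-events)
  and rejected rather than reported as a huge coefficient.
* **Bland–Altman**: differences are method-under-test minus ultrasound
  (positive mean = overestimation); sample SD uses the n−1 denominator;
  the bias test is a two-sided one-sample t-test; zero variance with
  nonzero mean reports `p = 0` with a warning.
* **Bootstrap**: m-out-of-n simple random sampling with replacement as
  stated (m = 1,500 regardless of n); replicates whose two-stage fit
  fails (typically event-free resamples of a 1% outcome) are dropped and
  counted, with a hard error above 10% failures. Seeds: one master seed
  is split deterministically into per-stage streams; all package RNG is
  wrapped so the caller's `.Random.seed` is untouched.
* **Complete-case handling** throughout; each agreement row and each
  association fit uses its own pairwise-complete set, so row `n`s
  differ. No imputation.

## Design decisions that were genuinely open

* The minimum fit size is `n ≥ p + 2` with `p` counting predictors
  excluding the intercept (so a 3-point single-predictor calibration is
  admissible).
* Outcome models are univariable (GA only); covariates influence the
  analysis only through the calibration stage. This mirrors a reported
  one-log-OR-per-method table structure.
* The availability sensitivity analysis restricts to records with all
  three measurements, masks ultrasound once per fraction by default
  (`redraw_mask = TRUE` redraws inside every bootstrap replicate), and
  inherits the full bootstrap.
* Haemoglobin and MUAC enter the calibration model linearly.
* Trimming is applied before the complete-case restriction.

## Known limitations

* The attenuation identity `λ_Q ≈ λ_T·σ_T²/(σ_T²+σ_δ²)` is exact for
  linear models and only approximate for logistic ones; at the default
  effect size (|λ_T| = 0.2) the approximation error is well below
  Monte-Carlo noise, which is why tests can use it as an oracle.
* With a small validation fraction, per-replicate calibration fits are
  estimated on few records; their sampling noise acts as extra
  measurement error in the constructed exposure, which *shrinks* the
  replicate log ORs and their spread even as the calibration-coefficient
  uncertainty grows. In this package's stated world the two effects
  nearly cancel, so the bootstrap SE is not reliably larger at 25%
  ultrasound availability than at 100% (see the acceptance notes); in
  real cohorts with correlated covariates the inflation channel can
  dominate. The qualitative advice — more ultrasound gives more precise
  calibrated estimates — still holds for the point estimates.
* Calibration coefficients are not transferable across settings without
  revalidation; the package offers no transfer procedure.
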