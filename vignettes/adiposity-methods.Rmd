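---
title: "Methods: body-fat batteries, risk screening, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: body-fat batteries, risk screening, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

# The problem

Adolescent adiposity is routinely estimated from anthropometry because
reference methods (DXA, densitometry) are impractical in the field. Published
prediction equations differ in their inputs (skinfolds, BMI, bioimpedance
resistance), their calibration populations, and their branching by sex, age,
race group and maturation stage — and they disagree substantially on the same
subject. `adipoquant` implements a twelve-method battery, the derived
cardiometabolic biomarkers and clinical risk flags, and the multi-stage
regression screen that ranks the methods by how many risk factors each
predicts. A calibrated synthetic-cohort generator makes every stage testable
without subject-level data, which no public repository provides for this
design.

# The body-fat battery

Three estimation families share one output contract (`percent_fat`, with
`density`, `ffm`, `fat_mass` where applicable):

* **Densitometric** (`EQ1`, `EQ5`): body density `D` is linear in the decimal
  logarithm of the four-fold sum (biceps + triceps + suprailiac +
  subscapular). `EQ1` converts by Siri's two-compartment formula
  `%BF = (4.95/D − 4.50)·100`; `EQ5` uses an age-adjusted conversion and an
  age-adjusted density. All `log` terms in the battery are **log10** — the
  densitometric convention — and the choice is centralised in one helper.
* **Direct regressions** (`EQ2`, `EQ3`, `EQ4`, `EQ7`, `EQ8`, `EQ10`):
  polynomials in skinfold sums, or linear forms in BMI/age or weight/height/
  age, with sex-specific coefficient sets and, for `EQ4` and `EQ10`, race- and
  maturation-specific intercepts.
* **Fat-free-mass predictions** (`EQ6`, `EQ9`, `BIA1`): FFM from weight,
  skinfolds and the resistance index `Ht²/R`; then exactly
  `fat_mass = weight − FFM` and `%BF = 100·fat_mass/weight`, so mass
  conservation holds to machine precision by construction.

Decisions the sources leave open, and how this package resolves them:

* **`EQ5` parenthesisation.** The printed expressions drop closing brackets.
  We adopt the reading `%BF = (562 − 4.2[A−2])/D − (525 − 4.7[A−2])` (male)
  and `%BF = (553 − 7.3[A−10])/D − (514 − 8.0[A−10])` (female), i.e. the
  age-adjusted numerator divided by density minus an age-adjusted constant —
  the only reading that reduces to a Siri-like form and stays monotone in the
  fold sum. The female density footnote mixes an `[A−10]` additive anchor
  with an `[A−2]` multiplier anchor; the default follows it verbatim
  (`eq5_female_density_variant = "printed"`), with an `"age10"` switch for
  the internally consistent variant.
* **The 35 mm switch in `EQ4`** is genuinely discontinuous; a sum of exactly
  35 mm is assigned to the quadratic branch. The tests assert the documented
  jump, not continuity.
* **Arm muscle circumference** for male `EQ6` is derived as
  `brachial perimeter − π·triceps/10` (cm), the standard caliper-and-tape
  derivation, exposed as `arm_muscle_circumference()`.
* **Out-of-range estimates** (negative, or ≥ 100%) are retained and flagged
  (`out_of_range`), never clamped: downstream reporting must be able to see
  them. `EQ2`'s printed quadratic peaks at a fold sum of 56.25 mm and
  declines beyond it; this is a property of the published equation and is
  documented rather than "fixed".
* **Excess fat** is classified at sex-specific %BF thresholds (defaults
  ≥ 20% male, ≥ 25% female, boundary inclusive, configurable): the
  "risk of overweight" and "overweight" strata of the child/adolescent
  classification are pooled, and the published cutoff tables do not pin a
  single number, so it is a parameter.
* **Ages**: decimal age enters formulas arithmetically; categorical branches
  (the 15–16 / 17–18 split of `EQ1`, the ≤ 15 / ≥ 16 split of `EQ8`) use
  completed years. The `nonwhite` race group maps to the black-coefficient
  forms of `EQ4`/`EQ10` (configurable).
* **`BIA1`** is a horizontal tetra-polar device whose manufacturer equation
  is proprietary; per the study procedure its resistance feeds a published
  FFM equation, by default `EQ9` (the only resistance equation defined for
  both sexes here), configurable to `EQ6`. `BIA2` (vertical 8-electrode) is a
  direct %BF reading taken as input.

Missing measurements surface as structured skips in `evaluate_battery()`
(`skip_reason` naming the field), or as errors in the single-method
functions and under `strict = TRUE`.

# Biomarkers and risk flags

Derived quantities are pure functions of the measured panel: Friedewald LDL
`TC − HDL − TG/5` (left missing, with a warning, when TG ≥ 400 mg/dL or the
triple is incoherent enough to make the estimate non-positive), the TC/HDL
and LDL/HDL ratios, and HOMA-IR `insulin × glucose / 405`. The 405 constant
is the mass-unit (mg/dL × µU/mL) convention; the study's insulin unit is
treated as µU/mL, since the µU/dL occasionally printed alongside would put
HOMA-IR two orders of magnitude off the reported group means (1.9 and 2.7,
which the constant 405 reproduces exactly).

Risk flags keep the printed comparators exactly: TC ≥ 150, LDL ≥ 100,
HDL ≤ 45, TG ≥ 100 mg/dL, HOMA-IR ≥ 3.16, SBP/DBP ≥ 120/80 mmHg, uric acid
strictly above the sex-specific reference bound (7.0 boys / 6.0 girls; a
pooled > 7 rule is available). Fasting-glucose (default ≥ 100 mg/dL) and
hyperinsulinemia (default ≥ 15 µU/mL) cutoffs are guideline values not
printed numerically in the source tables, so both are configurable.
`risk_count` counts the nine component flags; a component that cannot be
derived (missing LDL) contributes nothing. Presentation rounding is
one-decimal half-up (`round_half_up()`); full precision is kept internally.

The enrollment calculator uses `n₀ = z²p(1−p)/d²` with the finite-population
correction `n = n₀/(1 + (n₀−1)/N)`, rounded up.

# The association pipeline

For each (method, outcome) pair within a study group:

1. Right-skewed outcomes (TG, insulin, HOMA-IR, LDL, TC, both ratios) are
   log10-transformed; slopes for them are reported on that scale.
2. A bivariate OLS of the outcome on %BF admits the pair when the slope's
   P < 0.20 (strict).
3. Admitted pairs are refitted with covariates: sex (male = 1), and in the
   eutrophic group also the "normal-weight with excess body fat" indicator —
   `classify_excess_fat()` applied to a reference method, default `EQ5`
   (the source does not name the defining method; it is a parameter).
4. Shapiro–Wilk on residuals gates reporting: `assumptions_met` is
   `P > 0.05`, and gated cells carry the machine-readable reason
   `failed_assumptions` (the analogue of dashed cells in a printed table).
5. The White test (auxiliary regression of squared residuals on regressors,
   squares and cross-products; `n·R²` against χ²) triggers, at the 5% level,
   robust inference for the %BF coefficient via a small-sample
   heteroskedasticity-consistent covariance — HC3 by default, HC1/HC2
   configurable.
6. The maximum VIF over non-intercept regressors (`1/(1−R²ⱼ)`) is reported.

`rank_methods()` orders methods by the count of outcomes with
`assumptions_met` and P < 0.05 (strict), breaking ties by mean adjusted R²
over the significant cells and then by canonical method order — purely for
determinism. **No multiple-testing correction is applied**, faithful to the
original procedure; every P value is reported so a reader can apply one.

The normality utility for choosing t-test vs Mann–Whitney uses the
Lilliefors-corrected Kolmogorov–Smirnov test: with mean and SD estimated
from the data the uncorrected KS is anti-conservative and would contradict
the use of nonparametric tests for the skewed variables.

# The synthetic cohort generator

`generate_cohort()` emulates the two-group cross-sectional design: 140
eutrophic / 70 overweight adolescents, 52.4% female, 61.4% non-white, all
postpubescent. Per group, each biomarker has a target mean and SD:
triglycerides, insulin and uric acid are lognormal via exact mean/SD
inversion (`σ² = log(1 + s²/m²)`, `µ = log m − σ²/2`); the symmetric
biomarkers are Gaussian. Dependence enters through a Gaussian copula with a
configurable correlation matrix. Two deliberate design points:

* **No hard truncation of biomarkers.** The published min–max are the
  observed extremes of samples of size 140/70, not population bounds.
  Hard-truncating at them makes every outcome light-tailed, which
  under-disperses OLS t-statistics and visibly de-calibrates the pipeline's
  null rates; with population-faithful draws, sample extremes land near the
  published ranges on their own. Age is the exception — enrolment used a
  fixed age window, a genuine eligibility bound — and age is drawn from a
  truncated normal whose underlying parameters are solved numerically so the
  *truncated* mean/SD hit the targets. Infeasible targets (mean outside the
  window, an SD the window cannot hold, Gaussian mass below the positivity
  bound) raise a spec error up front. Gaussian draws are floored at half the
  observed minimum; the feasibility guard keeps the mass involved below
  10⁻³.
* **Default correlations are anchored to derivable quantities.** TC–HDL and
  TC–TG are set to 0.35 so that the *derived* Friedewald LDL reproduces the
  reported LDL dispersion (SD ≈ 23 mg/dL) and stays well away from zero;
  TG–insulin, glucose–insulin and SBP–DBP carry modest physiological values.
  LDL, HOMA-IR and the ratios are always computed from the drawn measured
  fields — never drawn — so the derivation identities hold by construction.

Anthropometry is driven by a latent adiposity factor `z`: the six skinfolds
are lognormal with fold-specific loadings (0.26–0.38) and noises
(0.21–0.28), weight couples to `z` with ρ = 0.72 and resistance with a
loading of 0.08 — levels chosen to mirror the empirically observed agreement
between BMI/BIA-based and skinfold-based %BF (correlations around 0.7–0.9)
and the material disagreement in who is classified as carrying excess fat.
Methods computed from the same four-fold sum (`EQ1`, `EQ5`, `EQ7`)
necessarily correlate above 0.97: that is a property of the equations, not
of the generator.

Planted effects (`effects` in `cohort_spec()`) inject
`outcome = baseline + slope·(%BF − group mean) + noise` on the outcome's
**analysis scale**: additive for Gaussian outcomes, on log10 for the
log-analysed ones (multiplicative on the raw scale, the standard model for
lognormal analytes). Centring within group preserves the group-level moment
targets. `plant_null()` zeroes every slope and injection noise, and is
idempotent. The generator makes *no* claim to reproduce the study's 76.7%
any-risk prevalence: that depends on joint dependence structure the
published tables cannot identify; the tests assert instead that prevalence
responds monotonically to the biomarker dispersion multiplier.

# Calibration and power experiments

The experiment drivers (`calibration_experiment()`, `ranking_experiment()`,
`slope_recovery_experiment()`, `white_power_experiment()`) run the real
pipeline on generated cohorts and are what the acceptance checks execute.
Problem sizes: 1,000 null cohorts for calibration, 100 cohorts for ranking
recovery, 500 regressions for slope recovery, 200 for White-test power.

* **Type-I calibration is stage-wise.** Under a global null the bivariate
  screen admits ≈ 20% of cells and the adjusted model rejects ≈ 5% — each
  stage at its nominal level. The end-to-end significant-cell rate of the
  gated pipeline is deliberately *lower* (≈ 2%): a cell must pass the
  screen, the residual-normality gate, and the 5% test, and the gates are
  not error-rate events. The experiment reports all three rates.
* **Ranking recovery needed a power analysis.** With a planted `EQ5` signal
  on TG, DBP and insulin at the reported magnitudes (R² ≈ 0.51 for insulin,
  ≈ 0.12 for TG and DBP), the study-sized eutrophic arm (n = 140) recovers
  the driver only about half the time: same-input methods are
  near-collinear proxies, and on null outcomes chance significance decides
  count ties. Two design consequences, fixed before the experiment was
  frozen: the ranking is evaluated over the planted outcomes (isolating
  signal recovery from fluke counts), and the arm is enlarged to n = 500.
  Injection noise equal to twice the baseline SD keeps all residuals
  near-normal; without it the Shapiro gate systematically punishes the
  *true* method, whose residuals are the purest and therefore show the
  baseline's shape most clearly — a subtle and instructive pathology of
  normality-gated model selection.
* **Slope recovery** uses the reported effect scale (log-slope 0.006 per
  %BF, R² ≈ 0.06, n = 140); OLS is unbiased, so mean bias within 10% is a
  Monte-Carlo statement.
* **White-test power** uses error SD proportional to %BF at n = 140; the
  trigger and `robust_se` are asserted to be the same event.

# What passing tests do and do not show

The generator produces clean, single-measurement data with a one-factor
adiposity structure, Gaussian/lognormal marginals and no measurement-error
protocol (the duplicate-measurement rules of field anthropometry are out of
scope), no pubertal growth dynamics, and no unmodelled confounding beyond
sex. Green tests therefore demonstrate that the *procedure* is implemented
correctly and is calibrated on data satisfying its assumptions — not that
any particular equation will rank first in a new population. The source
cohort's regression coefficients are not reproducible without its raw
subject data, which was never deposited; the pipeline is validated
structurally (calibration, recovery, power) instead.

Numerical conventions: density is carried in g/mL (the printed coefficient
scale), heights in cm except inside BMI, P thresholds are strict
inequalities, cutoff comparators are inclusive exactly as printed, and every
simulation seed derives from a single master seed so all experiments are
exactly reproducible.
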