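# adipoquant

Body-fat estimation batteries and cardiometabolic risk screening for
adolescent cohorts.

BMI alone cannot separate excess body fat from fat-free mass, so a
normal-weight adolescent can carry an adult's worth of adiposity — and its
metabolic consequences — undetected. Field studies therefore estimate the
percentage of body fat (%BF) from anthropometry: skinfold thicknesses,
weight, height, age, and bioelectrical impedance. Many published prediction
equations exist, and they disagree; the practical question is which of them
best predicts the cardiovascular risk profile (lipids, insulin resistance,
blood pressure, uric acid) in a given population. `adipoquant` implements
that entire analysis as a tested, reusable package:

* **Body-fat battery** (`evaluate_battery()`): ten anthropometric prediction
  equations (`EQ1`–`EQ10`) plus two bioimpedance estimates (`BIA1`, `BIA2`),
  with all sex / age / race / maturation branching. Three families:

  * *densitometric*: body density from the log10 four-skinfold sum, e.g.
    `D = 1.1533 − 0.0643·log₁₀(Σ4 folds)`, converted by Siri's
    two-compartment formula `%BF = (4.95/D − 4.50) × 100` (`EQ1`), or by an
    age-adjusted analogue (`EQ5`);
  * *direct regressions* of %BF or fat mass on skinfolds, BMI, age
    (`EQ2`–`EQ4`, `EQ7`, `EQ8`, `EQ10`);
  * *fat-free-mass (FFM) predictions* from the resistance index `Ht²/R`
    (`EQ6`, `EQ9`, `BIA1`), with `fat mass = weight − FFM` and
    `%BF = 100 · fat mass / weight`.

* **Derived biomarkers and risk flags** (`derive_panel()`, `risk_flags()`):
  Friedewald LDL (`TC − HDL − TG/5`, valid for TG < 400 mg/dL), lipid
  ratios, HOMA-IR (`insulin × glucose / 405`), and the clinical cutoffs
  (TC ≥ 150, LDL ≥ 100, HDL ≤ 45, TG ≥ 100 mg/dL, HOMA-IR ≥ 3.16,
  BP ≥ 120/80 mmHg, sex-specific uric acid), plus the finite-population
  sample-size formula for cross-sectional prevalence studies.

* **Association pipeline** (`build_association_matrix()`,
  `rank_methods()`): for every (method, outcome) pair, a bivariate OLS
  screen (admission at P < 0.20), then multiple regression adjusted for sex
  (and, among eutrophic subjects, for the "normal-weight with excess fat"
  indicator), gated by Shapiro–Wilk residual normality, checked for
  heteroskedasticity by the White test with small-sample robust (HC3)
  variances when it fires, and screened for multicollinearity by the
  variance inflation factor. Methods are ranked by the number of risk
  factors each predicts at P < 0.05.

* **Synthetic cohort generator** (`cohort_spec()`, `generate_cohort()`):
  reproducible two-group cohorts (140 eutrophic / 70 overweight by default)
  whose biomarker distributions match published group moments, with a latent
  adiposity factor linking anthropometry across methods and plantable
  %BF → outcome effects for calibration and power experiments.

## Worked example

One 16-year-old girl through the full battery:

```r
library(adipoquant)

adol <- tibble::tibble(
  subject_id = "A001", sex = "female", age = 16.4, race = "nonwhite",
  maturation = "postpubescent", weight = 58.3, height = 162.0,
  biceps = 9, triceps = 14, subscapular = 11, suprailiac = 12,
  midaxillary = 9, calf = 13, brachial_perimeter = 25.8, resistance = 588,
  bia2_percent_fat = 26.1, group = "eutrophic")

evaluate_battery(adol)[, c("method", "percent_fat", "ffm", "fat_mass", "excess_fat")]
#>    method percent_fat   ffm fat_mass excess_fat
#>  1 EQ1           27.1  NA       15.8 TRUE
#>  2 EQ2           23.8  NA       13.9 FALSE
#>  3 EQ3           21.6  NA       12.6 FALSE
#>  4 EQ4           22.6  NA       13.2 FALSE
#>  5 EQ5           22.9  NA       13.3 FALSE
#>  6 EQ6           24.2  44.2     14.1 FALSE
#>  7 EQ7           21.4  NA       12.5 FALSE
#>  8 EQ8           25.0  NA       14.6 TRUE
#>  9 EQ9           26.1  43.1     15.2 TRUE
#> 10 EQ10          30.0  NA       17.5 TRUE
#> 11 BIA1          26.1  43.1     15.2 TRUE
#> 12 BIA2          26.1  NA       15.2 TRUE
```

The twelve methods place her between 21.4% and 30.0% body fat, and disagree
on whether she crosses the female excess-fat threshold (25%) — exactly the
disagreement that motivates ranking the methods by clinical predictiveness.
Her fasting biochemistry:

```r
panel <- derive_panel(tibble::tibble(
  subject_id = "A001", glucose = 88, insulin = 11.4, tc = 158, hdl = 44,
  tg = 96, uric_acid = 4.1, sbp = 108, dbp = 66))
panel[, c("ldl", "tc_hdl_ratio", "ldl_hdl_ratio", "homa_ir")]
#>     ldl tc_hdl_ratio ldl_hdl_ratio homa_ir
#> 1  94.8         3.59          2.15    2.48

risk_flags(panel, "female")[, c("tc_high", "hdl_low", "risk_count", "any_risk")]
#>   tc_high hdl_low risk_count any_risk
#> 1 TRUE    TRUE             2 TRUE
```

Her LDL (94.8 mg/dL) and HOMA-IR (2.48) are below their cutoffs, but total
cholesterol ≥ 150 and HDL ≤ 45 each raise a flag: two risk factors. On a
whole cohort, `run_all(run_config(...))` chains simulation (or CSV input),
the battery, the risk panel, the per-group association grids and the method
ranking, and writes CSV artifacts plus a Markdown report.

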