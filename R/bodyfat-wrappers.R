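# Single-method entry points --------------------------------------------------
# Thin wrappers over evaluate_battery() so each estimation method can be run
# (and documented) on its own. With strict = TRUE (default) a missing required
# measurement raises an error naming the field; strict = FALSE returns the
# structured-skip rows instead.

single_method <- function(subjects, method, strict = TRUE, ...) {
  evaluate_battery(subjects, methods = method, strict = strict, ...)
}

#' Individual body-fat estimation methods
#'
#' One function per battery method; each returns the same estimate tibble as
#' [evaluate_battery()] restricted to that method.
#'
#' * `eq1_durnin()`: skinfold densitometry, four-fold log-sum density with Siri
#'   conversion; age 15-16 vs 17-18 coefficient sets (ages outside 15-18 are
#'   unsupported).
#' * `eq2_boileau()`: quadratic in triceps + subscapular.
#' * `eq3_slaughter_tc()`: linear in triceps + calf.
#' * `eq4_slaughter_ts()`: triceps + subscapular with a 35 mm branch switch;
#'   the male low-sum intercept depends on maturation stage and race group
#'   (exactly 35 mm is assigned to the quadratic branch).
#' * `eq5_weststrate()`: age-adjusted four-fold densitometry with an
#'   age-adjusted Siri-like conversion.
#' * `eq6_guo()`: sex-specific fat-free mass from weight, skinfolds, arm
#'   muscle circumference (males) and the resistance index height^2/R.
#' * `eq7_deurenberg90()`: sex-specific linear form in log10 four-fold sum.
#' * `eq8_deurenberg91()`: BMI, age and sex; child (<= 15 y) vs adolescent
#'   (>= 16 y) coefficient sets.
#' * `eq9_houtkooper()`: sex-common fat-free mass from height^2/R and weight.
#' * `eq10_ellis()`: fat mass (kg) from weight, height and age with
#'   sex-by-race coefficient sets.
#' * `bia1_percent_fat()`: the horizontal tetra-polar device's resistance fed
#'   into a configurable FFM prediction (default `EQ9`).
#'
#' @param subjects Subject table (see [validate_subjects()]).
#' @param strict Error on missing required measurements (default) instead of
#'   returning structured skips.
#' @param ... Passed on to [evaluate_battery()] (e.g.
#'   `eq5_female_density_variant`, `bia1_equation`, `nonwhite_as_black`).
#' @return Estimate tibble, one row per subject.
#' @name single_methods
NULL

#' @rdname single_methods
#' @export
eq1_durnin <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ1", strict, ...)

#' @rdname single_methods
#' @export
eq2_boileau <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ2", strict, ...)

#' @rdname single_methods
#' @export
eq3_slaughter_tc <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ3", strict, ...)

#' @rdname single_methods
#' @export
eq4_slaughter_ts <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ4", strict, ...)

#' @rdname single_methods
#' @export
eq5_weststrate <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ5", strict, ...)

#' @rdname single_methods
#' @export
eq6_guo <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ6", strict, ...)

#' @rdname single_methods
#' @export
eq7_deurenberg90 <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ7", strict, ...)

#' @rdname single_methods
#' @export
eq8_deurenberg91 <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ8", strict, ...)

#' @rdname single_methods
#' @export
eq9_houtkooper <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ9", strict, ...)

#' @rdname single_methods
#' @export
eq10_ellis <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "EQ10", strict, ...)

#' @rdname single_methods
#' @export
bia1_percent_fat <- function(subjects, strict = TRUE, ...)
  single_method(subjects, "BIA1", strict, ...)
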