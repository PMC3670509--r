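# Twelve-method adolescent body-fat battery ----------------------------------
#
# Ten anthropometric prediction equations plus two bioimpedance-derived
# estimates. Three families:
#   * densitometric: body density from skinfolds, converted to %BF by the
#     two-compartment Siri formula (EQ1) or an age-adjusted analogue (EQ5);
#   * direct skinfold / BMI regressions for %BF or fat mass (EQ2-EQ4, EQ7,
#     EQ8, EQ10);
#   * fat-free-mass predictions (EQ6, EQ9, BIA1): %BF derived from
#     fat mass = weight - FFM, %BF = 100 * fat mass / weight.
# All "log" terms are decimal logarithms (see skinfold_log()).

#' Siri two-compartment conversion from body density to percent fat
#'
#' \deqn{\%BF = (4.95 / D - 4.50) \times 100}
#'
#' @param density Body density in g/mL. Must lie in the physiological open
#'   interval (0.9, 1.2); values outside raise a domain error naming the bound.
#' @return Percent body fat (vectorised).
#' @export
#' @examples
#' siri_percent_fat(1.1)   # 0
#' siri_percent_fat(0.99)  # 100
siri_percent_fat <- function(density) {
  if (any(is.na(density))) {
    stop_adipoquant("density contains missing values", "adipoquant_domain_error")
  }
  if (any(density <= 0.9)) {
    stop_adipoquant(
      "density must exceed the lower physiological bound of 0.9 g/mL",
      "adipoquant_domain_error"
    )
  }
  if (any(density >= 1.2)) {
    stop_adipoquant(
      "density must be below the upper physiological bound of 1.2 g/mL",
      "adipoquant_domain_error"
    )
  }
  (4.95 / density - 4.50) * 100
}

#' Arm muscle circumference from brachial perimeter and triceps skinfold
#'
#' Standard derivation: brachial perimeter (cm) minus pi times the triceps
#' skinfold (converted from mm to cm). Used by the male fat-free-mass
#' prediction of `EQ6`.
#'
#' @param brachial_perimeter Mid-upper-arm circumference, cm.
#' @param triceps Triceps skinfold, mm.
#' @return Arm muscle circumference, cm (vectorised).
#' @export
arm_muscle_circumference <- function(brachial_perimeter, triceps) {
  brachial_perimeter - pi * triceps / 10
}

# Internal helpers ------------------------------------------------------------

# Per-row reason string when a required field is absent or NA; NA when usable.
missing_reason <- function(s, fields) {
  reason <- rep(NA_character_, nrow(s))
  for (f in rev(fields)) {
    miss <- if (!f %in% names(s)) rep(TRUE, nrow(s)) else is.na(s[[f]])
    reason[miss] <- paste0("missing measurement: ", f)
  }
  reason
}

blank_estimate <- function(s, method) {
  tibble(
    subject_id = s$subject_id,
    method = method,
    percent_fat = NA_real_,
    density = NA_real_,
    ffm = NA_real_,
    fat_mass = NA_real_,
    skip_reason = NA_character_
  )
}

# Fill fat_mass (and %BF <-> fat mass identities) once percent_fat is known.
finish_percent <- function(est, s) {
  ok <- !is.na(est$percent_fat)
  est$fat_mass[ok] <- est$percent_fat[ok] * s$weight[ok] / 100
  est
}

# For FFM-based methods the kg identities are primary and exact:
# fat_mass = weight - ffm, percent_fat = 100 * fat_mass / weight.
finish_ffm <- function(est, s) {
  ok <- !is.na(est$ffm)
  est$fat_mass[ok] <- s$weight[ok] - est$ffm[ok]
  est$percent_fat[ok] <- 100 * est$fat_mass[ok] / s$weight[ok]
  est
}

sum4_fields <- c("biceps", "triceps", "suprailiac", "subscapular")

# Method evaluators -----------------------------------------------------------
# Each returns the blank_estimate frame with computed rows filled in and
# skip_reason set for rows whose required inputs are missing or out of the
# branch coverage.

bf_eq1 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ1")
  est$skip_reason <- missing_reason(s, c("sex", "age", sum4_fields))
  ageyr <- floor(s$age)
  unsupported <- is.na(est$skip_reason) & (ageyr < 15 | ageyr > 18)
  est$skip_reason[unsupported] <-
    "unsupported age: densitometric coefficients cover 15-18 years"
  ok <- is.na(est$skip_reason)
  if (any(ok)) {
    sum4 <- rowSums(as.matrix(s[ok, sum4_fields, drop = FALSE]))
    young <- ageyr[ok] <= 16
    male <- s$sex[ok] == "male"
    c1 <- ifelse(young,
                 ifelse(male, 1.1533, 1.1369),
                 ifelse(male, 1.1620, 1.1549))
    c2 <- ifelse(young,
                 ifelse(male, 0.0643, 0.0598),
                 ifelse(male, 0.0630, 0.0678))
    d <- c1 - c2 * skinfold_log(sum4)
    est$density[ok] <- d
    est$percent_fat[ok] <- siri_percent_fat(d)
  }
  finish_percent(est, s)
}

bf_eq2 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ2")
  est$skip_reason <- missing_reason(s, c("sex", "triceps", "subscapular"))
  ok <- is.na(est$skip_reason)
  if (any(ok)) {
    ts <- s$triceps[ok] + s$subscapular[ok]
    const <- ifelse(s$sex[ok] == "male", -4.4, -2.4)
    est$percent_fat[ok] <- 1.35 * ts - 0.012 * ts^2 + const
  }
  finish_percent(est, s)
}

bf_eq3 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ3")
  est$skip_reason <- missing_reason(s, c("sex", "triceps", "calf"))
  ok <- is.na(est$skip_reason)
  if (any(ok)) {
    tc <- s$triceps[ok] + s$calf[ok]
    male <- s$sex[ok] == "male"
    est$percent_fat[ok] <- ifelse(male, 0.735 * tc + 1.0, 0.610 * tc + 5.1)
  }
  finish_percent(est, s)
}

# Male intercepts for the low-sum branch of EQ4, by race form and maturation.
slaughter_intercepts <- list(
  white = c(prepubescent = -1.7, pubescent = -3.4, postpubescent = -5.5),
  black = c(prepubescent = -3.5, pubescent = -5.2, postpubescent = -6.8)
)

bf_eq4 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ4")
  est$skip_reason <- missing_reason(s, c("sex", "triceps", "subscapular"))
  ok <- is.na(est$skip_reason)
  ts <- rep(NA_real_, nrow(s))
  ts[ok] <- s$triceps[ok] + s$subscapular[ok]
  # The 35 mm switch: exactly 35 mm is assigned to the quadratic branch.
  low <- ok & ts <= 35
  male <- s$sex == "male"
  need_cov <- low & male
  if (any(need_cov)) {
    cov_reason <- missing_reason(s, c("race", "maturation"))
    cov_reason[!is.na(cov_reason)] <- sub(
      "missing measurement", "missing covariate", cov_reason[!is.na(cov_reason)]
    )
    est$skip_reason[need_cov & !is.na(cov_reason)] <-
      cov_reason[need_cov & !is.na(cov_reason)]
    low <- low & is.na(est$skip_reason)
  }
  ok <- ok & is.na(est$skip_reason)
  lowm <- low & male & ok
  if (any(lowm)) {
    form <- ifelse(cfg$nonwhite_as_black & s$race[lowm] == "nonwhite",
                   "black", "white")
    icpt <- mapply(function(f, m) slaughter_intercepts[[f]][[m]],
                   form, s$maturation[lowm])
    est$percent_fat[lowm] <- 1.21 * ts[lowm] - 0.008 * ts[lowm]^2 + icpt
  }
  lowf <- low & !male & ok
  est$percent_fat[lowf] <- 1.33 * ts[lowf] - 0.013 * ts[lowf]^2 - 2.5
  hi <- ok & ts > 35
  est$percent_fat[hi & male] <- 0.783 * ts[hi & male] + 1.6
  est$percent_fat[hi & !male] <- 0.546 * ts[hi & !male] + 9.7
  finish_percent(est, s)
}

bf_eq5 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ5")
  est$skip_reason <- missing_reason(s, c("sex", "age", sum4_fields))
  male <- s$sex == "male"
  bad_age <- is.na(est$skip_reason) &
    ((male & s$age < 2) | (!male & s$age < 10))
  est$skip_reason[bad_age] <-
    "unsupported age: below the age anchor of the density formula"
  ok <- is.na(est$skip_reason)
  if (any(ok)) {
    sum4 <- rowSums(as.matrix(s[ok, sum4_fields, drop = FALSE]))
    a <- s$age[ok]
    m <- male[ok]
    lg <- skinfold_log(sum4)
    # Female density multiplier: the source prints the log coefficient anchored
    # at age 2 while the additive term is anchored at age 10; "printed" follows
    # that verbatim, "age10" uses the age-10 anchor throughout.
    f_mult_anchor <- if (cfg$eq5_female_density_variant == "age10") 10 else 2
    d <- ifelse(
      m,
      (1.1315 + 0.0018 * (a - 2)) - (0.0719 - 0.0006 * (a - 2)) * lg,
      (1.1350 + 0.0031 * (a - 10)) -
        (0.0719 - 0.0003 * (a - f_mult_anchor)) * lg
    )
    pbf <- ifelse(
      m,
      (562 - 4.2 * (a - 2)) / d - (525 - 4.7 * (a - 2)),
      (553 - 7.3 * (a - 10)) / d - (514 - 8.0 * (a - 10))
    )
    est$density[ok] <- d
    est$percent_fat[ok] <- pbf
  }
  finish_percent(est, s)
}

bf_eq6 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ6")
  base <- c("sex", "weight", "height", "resistance", "calf", "midaxillary")
  est$skip_reason <- missing_reason(s, base)
  male <- s$sex == "male"
  m_extra <- missing_reason(s, c("brachial_perimeter", "triceps"))
  f_extra <- missing_reason(s, c("triceps", "subscapular"))
  need_m <- is.na(est$skip_reason) & male & !is.na(m_extra)
  est$skip_reason[need_m] <- m_extra[need_m]
  need_f <- is.na(est$skip_reason) & !male & !is.na(f_extra)
  est$skip_reason[need_f] <- f_extra[need_f]
  ok <- is.na(est$skip_reason)
  if (any(ok)) {
    ht2r <- s$height[ok]^2 / s$resistance[ok]
    m <- male[ok]
    amc <- rep(NA_real_, sum(ok))
    amc[m] <- arm_muscle_circumference(s$brachial_perimeter[ok][m],
                                       s$triceps[ok][m])
    ffm <- ifelse(
      m,
      0.646 * s$weight[ok] - 0.116 * s$calf[ok] - 0.375 * s$midaxillary[ok] +
        0.475 * amc + 0.156 * ht2r - 2.932,
      0.682 * s$weight[ok] - 0.185 * s$calf[ok] - 0.244 * s$triceps[ok] -
        0.202 * s$subscapular[ok] + 0.182 * ht2r + 4.338
    )
    est$ffm[ok] <- ffm
  }
  finish_ffm(est, s)
}

bf_eq7 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ7")
  est$skip_reason <- missing_reason(s, c("sex", sum4_fields))
  ok <- is.na(est$skip_reason)
  if (any(ok)) {
    lg <- skinfold_log(rowSums(as.matrix(s[ok, sum4_fields, drop = FALSE])))
    male <- s$sex[ok] == "male"
    est$percent_fat[ok] <- ifelse(male,
                                  18.88 * lg - 15.58,
                                  39.02 * lg - 43.49)
  }
  finish_percent(est, s)
}

bf_eq8 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ8")
  est$skip_reason <- missing_reason(s, c("sex", "age", "weight", "height"))
  ok <- is.na(est$skip_reason)
  if (any(ok)) {
    bmi_v <- bmi(s$weight[ok], s$height[ok])
    a <- s$age[ok]
    sx <- as.numeric(s$sex[ok] == "male")
    child <- floor(a) <= 15
    est$percent_fat[ok] <- ifelse(
      child,
      1.51 * bmi_v - 0.70 * a - 3.6 * sx + 1.4,
      1.2 * bmi_v + 0.23 * a - 10.8 * sx - 5.4
    )
  }
  finish_percent(est, s)
}

bf_eq9 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ9")
  est$skip_reason <- missing_reason(s, c("weight", "height", "resistance"))
  ok <- is.na(est$skip_reason)
  if (any(ok)) {
    est$ffm[ok] <- 0.61 * s$height[ok]^2 / s$resistance[ok] +
      0.25 * s$weight[ok] + 1.31
  }
  finish_ffm(est, s)
}

bf_eq10 <- function(s, cfg) {
  est <- blank_estimate(s, "EQ10")
  est$skip_reason <- missing_reason(s, c("sex", "weight", "age"))
  race_reason <- missing_reason(s, "race")
  need_race <- is.na(est$skip_reason) & !is.na(race_reason)
  est$skip_reason[need_race] <- "missing covariate: race"
  male <- s$sex == "male"
  race <- if ("race" %in% names(s)) s$race else rep(NA_character_, nrow(s))
  black <- cfg$nonwhite_as_black & !is.na(race) & race == "nonwhite"
  # height enters every form except the white-male one
  need_ht <- is.na(est$skip_reason) & (!male | black)
  ht_reason <- missing_reason(s, "height")
  est$skip_reason[need_ht & !is.na(ht_reason)] <-
    ht_reason[need_ht & !is.na(ht_reason)]
  ok <- is.na(est$skip_reason)
  if (any(ok)) {
    w <- s$weight[ok]; a <- s$age[ok]; h <- s$height
    m <- male[ok]; b <- black[ok]
    f_kg <- rep(NA_real_, sum(ok))
    f_kg[m & !b] <- 0.534 * w[m & !b] - 1.59 * a[m & !b] + 3.03
    f_kg[m & b] <- 0.594 * w[m & b] - 0.381 * h[ok][m & b] + 36.0
    f_kg[!m & !b] <- 0.642 * w[!m & !b] - 0.120 * h[ok][!m & !b] -
      0.606 * a[!m & !b] + 8.98
    f_kg[!m & b] <- 0.653 * w[!m & b] - 0.163 * h[ok][!m & b] -
      0.298 * a[!m & b] + 10.7
    est$fat_mass[ok] <- f_kg
    est$percent_fat[ok] <- 100 * f_kg / w
  }
  est
}

bf_bia1 <- function(s, cfg) {
  eq <- match.arg(cfg$bia1_equation, c("EQ9", "EQ6"))
  est <- if (eq == "EQ9") bf_eq9(s, cfg) else bf_eq6(s, cfg)
  est$method <- "BIA1"
  est
}

bf_bia2 <- function(s, cfg) {
  est <- blank_estimate(s, "BIA2")
  est$skip_reason <- missing_reason(s, "bia2_percent_fat")
  ok <- is.na(est$skip_reason)
  est$percent_fat[ok] <- s$bia2_percent_fat[ok]
  finish_percent(est, s)
}

bf_evaluators <- list(
  EQ1 = bf_eq1, EQ2 = bf_eq2, EQ3 = bf_eq3, EQ4 = bf_eq4, EQ5 = bf_eq5,
  EQ6 = bf_eq6, EQ7 = bf_eq7, EQ8 = bf_eq8, EQ9 = bf_eq9, EQ10 = bf_eq10,
  BIA1 = bf_bia1, BIA2 = bf_bia2
)

battery_config <- function(bia1_equation = "EQ9",
                           eq5_female_density_variant = "printed",
                           nonwhite_as_black = TRUE) {
  list(
    bia1_equation = bia1_equation,
    eq5_female_density_variant =
      match.arg(eq5_female_density_variant, c("printed", "age10")),
    nonwhite_as_black = isTRUE(nonwhite_as_black)
  )
}

#' Classify excess body fat from a percent-fat estimate
#'
#' Dichotomises percent body fat at the sex-specific "risk of overweight"
#' threshold of the Lohman child/adolescent classification; adolescents at or
#' above the threshold are treated as carrying excess body fat (the "risk of
#' overweight" and "overweight" strata are pooled). The source cutoff values
#' are not fixed by the classification tables alone, so the thresholds are
#' configurable; defaults are 20% (male) and 25% (female), boundary inclusive.
#'
#' @param percent_fat Percent body fat (vectorised).
#' @param sex `"male"`/`"female"`, recycled against `percent_fat`.
#' @param thresholds Named numeric vector with elements `male` and `female`.
#' @return Logical vector; `NA` where `percent_fat` is `NA`.
#' @export
#' @examples
#' classify_excess_fat(c(19.9, 20), "male") # FALSE TRUE
classify_excess_fat <- function(percent_fat, sex,
                                thresholds = c(male = 20, female = 25)) {
  stopifnot(all(c("male", "female") %in% names(thresholds)))
  percent_fat >= unname(thresholds[ifelse(sex == "male", "male", "female")])
}

#' Evaluate the body-fat estimation battery
#'
#' Runs the requested estimation methods on every subject, returning one row
#' per (subject, method) in the canonical method order. Methods whose required
#' measurements are missing for a subject are reported as structured skips
#' (`skip_reason` filled, estimate columns `NA`), never silently dropped;
#' `strict = TRUE` turns any skip into an error.
#'
#' Out-of-range raw estimates (negative or >= 100 percent) are retained and
#' flagged via `out_of_range` rather than clamped, so downstream reporting can
#' surface them.
#'
#' @param subjects Subject table (see [validate_subjects()]).
#' @param methods `"all"` or a character vector of method ids from
#'   [bf_methods()]. Must be non-empty.
#' @param bia1_equation Fat-free-mass prediction bound to the horizontal
#'   tetra-polar device's resistance output: `"EQ9"` (default; the only
#'   resistance-based FFM equation defined for both sexes) or `"EQ6"`.
#' @param eq5_female_density_variant `"printed"` (default) follows the source's
#'   female density footnote verbatim (log-term coefficient anchored at age 2);
#'   `"age10"` anchors it at age 10, consistent with the additive term.
#' @param excess_fat_thresholds Passed to [classify_excess_fat()].
#' @param nonwhite_as_black Map the `nonwhite` race group to the
#'   black-coefficient forms of `EQ4` and `EQ10` (default `TRUE`).
#' @param strict Error on any skipped (subject, method) pair.
#' @return Tibble with columns `subject_id`, `method`, `percent_fat`,
#'   `density` (densitometric methods only), `ffm` (FFM-based methods only),
#'   `fat_mass`, `out_of_range`, `excess_fat`, `skip_reason`.
#' @export
evaluate_battery <- function(subjects, methods = "all",
                             bia1_equation = "EQ9",
                             eq5_female_density_variant = "printed",
                             excess_fat_thresholds = c(male = 20, female = 25),
                             nonwhite_as_black = TRUE,
                             strict = FALSE) {
  assert_valid_subjects(subjects)
  if (identical(methods, "all")) methods <- bf_methods()
  if (length(methods) == 0) {
    stop_adipoquant("`methods` must name at least one estimation method",
                    "adipoquant_usage_error")
  }
  bad <- setdiff(methods, bf_methods())
  if (length(bad) > 0) {
    stop_adipoquant(paste0("unknown method id(s): ", paste(bad, collapse = ", ")),
                    "adipoquant_usage_error")
  }
  methods <- bf_methods()[bf_methods() %in% methods]
  cfg <- battery_config(bia1_equation, eq5_female_density_variant,
                        nonwhite_as_black)
  s <- as_tibble(subjects)
  out <- dplyr::bind_rows(lapply(methods, function(m) bf_evaluators[[m]](s, cfg)))
  out$out_of_range <- !is.na(out$percent_fat) &
    (out$percent_fat < 0 | out$percent_fat >= 100)
  sex_by_id <- setNames(as.character(s$sex), as.character(s$subject_id))
  out$excess_fat <- classify_excess_fat(
    out$percent_fat, sex_by_id[as.character(out$subject_id)],
    excess_fat_thresholds
  )
  if (strict && any(!is.na(out$skip_reason))) {
    sk <- out[!is.na(out$skip_reason), ]
    stop_adipoquant(
      paste0("skipped estimates in strict mode: ",
             paste0(sk$method, "/", sk$subject_id, " (", sk$skip_reason, ")",
                    collapse = "; ")),
      "adipoquant_skip_error"
    )
  }
  out[, c("subject_id", "method", "percent_fat", "density", "ffm", "fat_mass",
          "out_of_range", "excess_fat", "skip_reason")]
}
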