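# Derived biomarkers and clinical risk flags ---------------------------------

#' Friedewald estimate of LDL cholesterol
#'
#' \deqn{LDL = TC - HDL - TG/5} (all mg/dL), valid only when triglycerides are
#' below 400 mg/dL.
#'
#' @param tc Total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param tg Triglycerides, mg/dL (must be < 400).
#' @return Estimated LDL, mg/dL (vectorised).
#' @export
#' @examples
#' friedewald_ldl(146.6, 48.9, 63.2) # 85.06
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tc <= 0 | hdl <= 0 | tg <= 0, na.rm = TRUE)) {
    stop_adipoquant("lipid inputs must be positive", "adipoquant_domain_error")
  }
  if (any(tg >= 400, na.rm = TRUE)) {
    stop_adipoquant(
      "triglycerides >= 400 mg/dL: Friedewald estimate invalid, supply measured LDL",
      "adipoquant_friedewald_error"
    )
  }
  tc - hdl - tg / 5
}

#' HOMA-IR insulin-resistance index
#'
#' Homeostasis-model index on the mass-unit scale:
#' \deqn{HOMA\mbox{-}IR = insulin \times glucose / 405}
#' with glucose in mg/dL and insulin in uU/mL.
#'
#' @param glucose Fasting glucose, mg/dL.
#' @param insulin Fasting insulin, uU/mL.
#' @return HOMA-IR (dimensionless, vectorised).
#' @export
#' @examples
#' homa_ir(84.0, 9.1) # 1.887
homa_ir <- function(glucose, insulin) {
  if (any(glucose <= 0 | insulin <= 0, na.rm = TRUE)) {
    stop_adipoquant("glucose and insulin must be positive",
                    "adipoquant_domain_error")
  }
  insulin * glucose / 405
}

#' Body mass index
#'
#' @param weight Weight, kg.
#' @param height Height, cm.
#' @return BMI, kg/m^2 (vectorised).
#' @export
bmi <- function(weight, height) {
  if (any(weight <= 0 | height <= 0, na.rm = TRUE)) {
    stop_adipoquant("weight and height must be positive",
                    "adipoquant_domain_error")
  }
  weight / (height / 100)^2
}

#' Derive the computed biomarker fields of a panel
#'
#' Adds (or recomputes) the derived columns of a fasting-biochemistry panel:
#' `ldl` (Friedewald), `tc_hdl_ratio`, `ldl_hdl_ratio` and `homa_ir`. Derived
#' fields are pure functions of the measured fields, so recomputation is
#' idempotent. Columns are named as in [risk_outcomes()]: `glucose`,
#' `insulin`, `tc`, `hdl`, `tg`, `uric_acid`, `sbp`, `dbp`.
#'
#' @param panel Data frame with the measured biomarker columns.
#' @return The panel as a tibble with derived columns filled in.
#' @export
derive_panel <- function(panel) {
  need <- c("glucose", "insulin", "tc", "hdl", "tg")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    stop_adipoquant(
      paste0("panel is missing measured column(s): ",
             paste(missing_cols, collapse = ", ")),
      "adipoquant_schema_error"
    )
  }
  panel <- as_tibble(panel)
  # Friedewald is undefined at TG >= 400 mg/dL; such subjects keep a missing
  # LDL (a measured LDL would be needed) rather than a biased estimate.
  valid <- panel$tg < 400
  if (!all(valid)) {
    warn(paste0(sum(!valid), " subject(s) with TG >= 400 mg/dL: ",
                "Friedewald LDL left missing"))
  }
  ldl <- ifelse(valid, panel$tc - panel$hdl - panel$tg / 5, NA_real_)
  # a non-positive estimate signals an incoherent lipid triple; keep it
  # missing rather than propagating a nonsense concentration
  if (any(!is.na(ldl) & ldl <= 0)) {
    warn(paste0(sum(!is.na(ldl) & ldl <= 0),
                " subject(s) with non-positive Friedewald LDL: left missing"))
    ldl[!is.na(ldl) & ldl <= 0] <- NA_real_
  }
  panel$ldl <- ldl
  panel$tc_hdl_ratio <- panel$tc / panel$hdl
  panel$ldl_hdl_ratio <- panel$ldl / panel$hdl
  panel$homa_ir <- homa_ir(panel$glucose, panel$insulin)
  panel
}

#' Clinical cutoffs for the cardiometabolic risk flags
#'
#' The printed comparator conventions are kept exactly: TC >= 150 mg/dL,
#' LDL >= 100 mg/dL, HDL <= 45 mg/dL, TG >= 100 mg/dL, HOMA-IR >= 3.16,
#' systolic/diastolic blood pressure >= 120/80 mmHg, and uric acid above the
#' sex-specific upper reference bound (> 7.0 mg/dL boys, > 6.0 mg/dL girls).
#' The fasting-glucose cutoff (ADA) and hyperinsulinemia cutoff are not
#' printed numerically in the source tables and default to >= 100 mg/dL and
#' >= 15 uU/mL respectively.
#'
#' @param tc,ldl,tg,glucose,insulin,homa Lower inclusive bounds flagged as high.
#' @param hdl Upper inclusive bound flagged as low.
#' @param uric_male,uric_female Strict upper bounds for uric acid by sex.
#' @param sbp,dbp Lower inclusive bounds for blood pressure.
#' @param uric_pooled Use the pooled "> 7 mg/dL" uric-acid rule for both sexes
#'   instead of the sex-specific bounds.
#' @return Named list of cutoffs.
#' @export
risk_cutoffs <- function(tc = 150, ldl = 100, hdl = 45, tg = 100,
                         glucose = 100, insulin = 15, homa = 3.16,
                         uric_male = 7.0, uric_female = 6.0,
                         sbp = 120, dbp = 80, uric_pooled = FALSE) {
  list(tc = tc, ldl = ldl, hdl = hdl, tg = tg, glucose = glucose,
       insulin = insulin, homa = homa, uric_male = uric_male,
       uric_female = uric_female, sbp = sbp, dbp = dbp,
       uric_pooled = isTRUE(uric_pooled))
}

#' Cardiometabolic risk flags for a biomarker panel
#'
#' Evaluates the component risk flags against [risk_cutoffs()] and aggregates
#' them: `any_risk` is the OR of the nine component flags and `risk_count`
#' their number.
#'
#' @param panel Biomarker panel with derived fields (see [derive_panel()]).
#' @param sex `"male"`/`"female"` per panel row (recycled if length one).
#' @param cutoffs A [risk_cutoffs()] list.
#' @return Tibble of logical component flags plus `any_risk` and `risk_count`
#'   (and `subject_id` when present in `panel`).
#' @export
risk_flags <- function(panel, sex, cutoffs = risk_cutoffs()) {
  need <- c("glucose", "insulin", "tc", "hdl", "tg", "uric_acid",
            "sbp", "dbp", "ldl", "homa_ir")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0) {
    stop_adipoquant(
      paste0("panel is missing column(s): ",
             paste(missing_cols, collapse = ", "),
             " (run derive_panel() first?)"),
      "adipoquant_schema_error"
    )
  }
  sex <- rep_len(sex, nrow(panel))
  uric_bound <- if (cutoffs$uric_pooled) {
    rep(cutoffs$uric_male, nrow(panel))
  } else {
    ifelse(sex == "male", cutoffs$uric_male, cutoffs$uric_female)
  }
  flags <- tibble(
    tc_high = panel$tc >= cutoffs$tc,
    ldl_high = panel$ldl >= cutoffs$ldl,
    hdl_low = panel$hdl <= cutoffs$hdl,
    tg_high = panel$tg >= cutoffs$tg,
    glucose_high = panel$glucose >= cutoffs$glucose,
    hyperinsulinemia = panel$insulin >= cutoffs$insulin,
    insulin_resistant = panel$homa_ir >= cutoffs$homa,
    uric_acid_high = panel$uric_acid > uric_bound,
    bp_high = panel$sbp >= cutoffs$sbp | panel$dbp >= cutoffs$dbp
  )
  # a missing component (e.g. LDL not derivable) contributes nothing rather
  # than poisoning the subject's aggregate
  flags$risk_count <- rowSums(flags, na.rm = TRUE)
  flags$any_risk <- flags$risk_count > 0
  if ("subject_id" %in% names(panel)) {
    flags <- dplyr::bind_cols(tibble(subject_id = panel$subject_id), flags)
  }
  flags
}

#' Minimum sample size for a cross-sectional prevalence study
#'
#' Normal-approximation sample size with finite-population correction:
#' \deqn{n_0 = z^2 p (1-p) / d^2, \quad n = n_0 / (1 + (n_0 - 1)/N)}
#' rounded up to the next whole subject. `z` is the two-sided normal quantile
#' for the requested confidence level.
#'
#' @param population Source population size `N`.
#' @param prevalence Anticipated prevalence `p` in (0, 1).
#' @param margin Acceptable absolute error `d` in (0, 1).
#' @param confidence Confidence level (default 0.95).
#' @return Integer minimum enrollment.
#' @export
#' @examples
#' cross_sectional_sample_size(5010, 0.50, 0.07, 0.95) # 189
cross_sectional_sample_size <- function(population, prevalence, margin,
                                        confidence = 0.95) {
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop_adipoquant("prevalence must lie strictly between 0 and 1",
                    "adipoquant_domain_error")
  }
  if (!is.finite(margin) || margin <= 0 || margin >= 1) {
    stop_adipoquant("margin must lie strictly between 0 and 1",
                    "adipoquant_domain_error")
  }
  if (population < 1) {
    stop_adipoquant("population must be at least 1", "adipoquant_domain_error")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * prevalence * (1 - prevalence) / margin^2
  n <- if (is.infinite(population)) n0 else n0 / (1 + (n0 - 1) / population)
  as.integer(ceiling(n))
}
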