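# Canonical orderings shared across modules ----------------------------------

#' Canonical body-fat method identifiers
#'
#' The twelve estimation methods in their stable reporting order: the ten
#' anthropometric prediction equations (`EQ1`..`EQ10`) followed by the two
#' bioimpedance-derived estimates (`BIA1`, horizontal tetra-polar device whose
#' resistance feeds a fat-free-mass prediction equation; `BIA2`, vertical
#' 8-electrode device read directly as percent fat).
#'
#' @return Character vector of method ids.
#' @export
#' @examples
#' bf_methods()
bf_methods <- function() {
  c(paste0("EQ", 1:10), "BIA1", "BIA2")
}

#' Canonical cardiometabolic outcome names
#'
#' The twelve outcomes screened against each body-fat method: fasting glucose,
#' total cholesterol, HDL, LDL, triglycerides, the TC/HDL and LDL/HDL ratios,
#' uric acid, insulin, HOMA-IR, and systolic/diastolic blood pressure.
#'
#' @return Character vector of outcome column names.
#' @export
risk_outcomes <- function() {
  c("glucose", "tc", "hdl", "ldl", "tg", "tc_hdl_ratio", "ldl_hdl_ratio",
    "uric_acid", "insulin", "homa_ir", "sbp", "dbp")
}

#' Outcomes analysed on the log10 scale
#'
#' The right-skewed outcomes that the regression pipeline log-transforms before
#' model fitting: TG, insulin, HOMA-IR, LDL, TC and the LDL/HDL and TC/HDL
#' ratios.
#'
#' @return Character vector, a subset of [risk_outcomes()].
#' @export
log_outcomes <- function() {
  c("tg", "insulin", "homa_ir", "ldl", "tc", "ldl_hdl_ratio", "tc_hdl_ratio")
}

# All "log" terms in the skinfold prediction equations are decimal logarithms
# (densitometry convention); centralised so the convention lives in one place.
skinfold_log <- function(x) log10(x)

#' Round half away from zero
#'
#' Presentation rounding used for reported tables (one decimal, half-up),
#' as opposed to base R's round-half-even. Raw precision is always retained
#' internally; this is applied only when formatting summaries.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(76.65, 1) # 76.7
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stop with a classed condition so callers can distinguish error families.
stop_adipoquant <- function(msg, class) {
  abort(msg, class = c(class, "adipoquant_error"))
}
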