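# Multi-stage regression screen ----------------------------------------------
#
# The analysis chain mirrors a two-stage epidemiological screen: each risk
# outcome is regressed on each method's percent fat (bivariate admission at
# P < 0.20), admitted pairs are refitted with covariate adjustment, model
# residuals are gated by Shapiro-Wilk normality, heteroskedasticity is tested
# with the White regression and, when present, inference switches to a
# small-sample robust covariance. Methods are finally ranked by how many
# outcomes they predict at P < 0.05.

#' Normality check with the Lilliefors-corrected Kolmogorov-Smirnov test
#'
#' Tests a sample against a normal distribution with mean and SD estimated
#' from the data. The Lilliefors correction is required because the plain
#' KS test is anti-conservative when parameters are estimated.
#'
#' @param values Numeric vector, n >= 8, non-degenerate.
#' @return List with `statistic`, `p_value` and `normal` (`p_value > 0.05`).
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 8) {
    stop_adipoquant("normality check requires at least 8 observations",
                    "adipoquant_domain_error")
  }
  if (sd(values) == 0) {
    stop_adipoquant("normality check undefined for a constant (zero-variance) vector",
                    "adipoquant_domain_error")
  }
  kt <- nortest::lillie.test(values)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       normal = kt$p.value > 0.05)
}

#' Two-group comparison with automatic test selection
#'
#' Equal-variance two-sided Student's t-test when the variable is normal,
#' Mann-Whitney (Wilcoxon rank-sum, normal approximation) otherwise.
#'
#' @param values Numeric vector.
#' @param groups Binary group labels aligned with `values`.
#' @param normal Logical; if `NULL`, decided by [normality_check()] on the
#'   pooled values.
#' @return List with `test_name` (`"student_t"` or `"mann_whitney"`),
#'   `statistic` and `p_value`.
#' @export
compare_groups <- function(values, groups, normal = NULL) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) != 2) {
    stop_adipoquant("`groups` must contain exactly two groups",
                    "adipoquant_domain_error")
  }
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop_adipoquant("each group needs at least 2 observations",
                    "adipoquant_domain_error")
  }
  if (is.null(normal)) normal <- normality_check(values)$normal
  if (normal) {
    tt <- t.test(x, y, var.equal = TRUE)
    list(test_name = "student_t", statistic = unname(tt$statistic),
         p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    list(test_name = "mann_whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value)
  }
}

#' Log10-transform the skewed outcomes of a panel
#'
#' Replaces the listed right-skewed outcomes by their decimal logarithms,
#' leaving all other columns untouched. The transformed columns are recorded
#' in the `"log_transformed"` attribute.
#'
#' @param panel Biomarker panel (derived fields computed).
#' @param outcomes Columns to transform; defaults to the intersection of
#'   [log_outcomes()] with the panel's columns.
#' @return The transformed panel.
#' @export
log_transform_outcomes <- function(panel,
                                   outcomes = intersect(log_outcomes(),
                                                        names(panel))) {
  for (col in outcomes) {
    v <- panel[[col]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) {
      who <- if ("subject_id" %in% names(panel)) {
        panel$subject_id[bad]
      } else {
        bad
      }
      stop_adipoquant(
        paste0("non-positive value in log-transformed outcome `", col,
               "` for subject(s): ", paste(who, collapse = ", ")),
        "adipoquant_domain_error"
      )
    }
    panel[[col]] <- log10(v)
  }
  attr(panel, "log_transformed") <- outcomes
  panel
}

#' Bivariate screening regression
#'
#' Ordinary least squares of one outcome (on its analysis scale) on one
#' method's percent fat. A pair is admitted to the adjusted stage when the
#' slope's P value is strictly below the screen threshold.
#'
#' @param percent_fat Predictor vector.
#' @param outcome Outcome vector (same length).
#' @param screen_threshold Admission threshold (default 0.20, strict).
#' @return One-row tibble with `beta`, `r_squared`, `p_value`, `n`, `admitted`.
#' @export
bivariate_screen <- function(percent_fat, outcome, screen_threshold = 0.20) {
  keep <- complete.cases(percent_fat, outcome)
  x <- percent_fat[keep]; y <- outcome[keep]
  if (length(x) < 10) {
    stop_adipoquant("bivariate screen requires at least 10 complete pairs",
                    "adipoquant_domain_error")
  }
  if (sd(x) == 0) {
    stop_adipoquant("percent fat has zero variance", "adipoquant_domain_error")
  }
  as_tibble(screen_ols(x, y, screen_threshold))
}

# simple-regression OLS in closed form (equivalent to lm(y ~ x); the test
# suite cross-checks the two routes)
screen_ols <- function(x, y, screen_threshold) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  beta <- sum(xc * yc) / sxx
  res <- yc - beta * xc
  rss <- sum(res^2)
  tss <- sum(yc^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * pt(-abs(beta / se), df = n - 2)
  list(beta = beta, r_squared = r2, p_value = p, n = n,
       admitted = p < screen_threshold)
}

#' White test for heteroskedasticity
#'
#' Regresses the squared residuals of a fitted linear model on the model's
#' regressors, their squares and pairwise cross-products; under
#' homoskedasticity n R-squared of that auxiliary regression is chi-squared
#' with degrees of freedom equal to its regressor rank. Redundant auxiliary
#' columns (e.g. the square of a binary indicator) are absorbed by the rank.
#'
#' @param model An `lm` fit.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
white_test <- function(model) {
  x <- model.matrix(model)
  white_test_mat(residuals(model),
                 x[, colnames(x) != "(Intercept)", drop = FALSE])
}

white_test_mat <- function(res, x) {
  u2 <- res^2
  k <- ncol(x)
  aux <- list(x, x^2)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        aux[[length(aux) + 1]] <- x[, i] * x[, j]
      }
    }
  }
  z <- cbind(1, do.call(cbind, aux))
  q <- qr(z)
  res <- qr.resid(q, u2)
  tss <- sum((u2 - mean(u2))^2)
  r2 <- 1 - sum(res^2) / tss
  df <- q$rank - 1
  stat <- length(u2) * r2
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Covariate-adjusted regression with assumption gates
#'
#' Fits OLS of an outcome on percent fat plus covariates, then audits the
#' classical assumptions: Shapiro-Wilk on residuals gates reporting
#' (`assumptions_met` is `residual_normality_p > 0.05`); the White test
#' triggers, at the 5% level, recomputation of the percent-fat SE and P value
#' with a small-sample robust covariance (HC3 by default); the maximum
#' variance inflation factor over non-intercept regressors gauges
#' multicollinearity.
#'
#' @param outcome Outcome vector (analysis scale).
#' @param percent_fat Predictor of interest.
#' @param covariates Optional data frame of additional regressors.
#' @param robust_type Robust covariance flavour: `"HC3"` (default), `"HC2"`,
#'   `"HC1"`.
#' @param white_alpha Significance level of the heteroskedasticity trigger.
#' @return One-row tibble with `beta`, `r_squared`, `p_value`, `n`,
#'   `adjusted_for`, `robust_se`, `residual_normality_p`, `white_test_p`,
#'   `vif_max`, `assumptions_met`.
#' @export
adjusted_regression <- function(outcome, percent_fat, covariates = NULL,
                                robust_type = c("HC3", "HC2", "HC1"),
                                white_alpha = 0.05) {
  as_tibble(adjust_ols(outcome, percent_fat, covariates,
                       match.arg(robust_type), white_alpha))
}

# QR-based workhorse behind adjusted_regression(); returns a plain list so
# the grid builder and the simulation experiments avoid per-cell tibble
# overhead. The robust branch defers to sandwich/lmtest on a real lm fit.
adjust_ols <- function(outcome, percent_fat, covariates, robust_type,
                       white_alpha) {
  has_cov <- !is.null(covariates) && NCOL(covariates) > 0
  cv <- if (has_cov) as.matrix(as.data.frame(covariates)) else NULL
  keep <- complete.cases(outcome, percent_fat)
  if (has_cov) keep <- keep & complete.cases(cv)
  n <- sum(keep)
  if (n < 10) {
    stop_adipoquant("adjusted regression requires at least 10 complete rows",
                    "adipoquant_domain_error")
  }
  x <- cbind(1, percent_fat[keep], if (has_cov) cv[keep, , drop = FALSE])
  colnames(x) <- c("(Intercept)", "percent_fat",
                   if (has_cov) colnames(cv))
  y <- outcome[keep]
  q <- qr(x)
  if (q$rank < ncol(x)) {
    dropped <- colnames(x)[q$pivot[seq(q$rank + 1, ncol(x))]]
    stop_adipoquant(
      paste0("design matrix is rank deficient; collinear column(s): ",
             paste(dropped, collapse = ", ")),
      "adipoquant_rank_error"
    )
  }
  coefs <- qr.coef(q, y)
  res <- qr.resid(q, y)
  p_par <- ncol(x)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p_par)
  xtx_inv <- chol2inv(qr.R(q))
  se <- sqrt(sigma2 * diag(xtx_inv))
  j <- which(colnames(x) == "percent_fat")
  tstat <- coefs[[j]] / se[j]
  p <- 2 * pt(-abs(tstat), df = n - p_par)

  sw <- shapiro.test(res)
  wt <- white_test_mat(res, x[, -1, drop = FALSE])
  robust <- wt$p_value < white_alpha
  if (robust) {
    dat <- as.data.frame(cbind(.outcome = y, x[, -1, drop = FALSE]))
    fit <- lm(.outcome ~ ., data = dat)
    ct <- lmtest::coeftest(fit,
                           vcov = sandwich::vcovHC(fit, type = robust_type))
    p <- ct["percent_fat", "Pr(>|t|)"]
  }
  k <- p_par - 1
  vif_max <- if (k >= 2) {
    max(diag(solve(stats::cor(x[, -1, drop = FALSE]))))
  } else {
    1
  }
  list(
    beta = coefs[[j]],
    r_squared = 1 - rss / tss,
    p_value = unname(p),
    n = n,
    adjusted_for = if (has_cov) paste(colnames(cv), collapse = "+") else "",
    robust_se = robust,
    residual_normality_p = sw$p.value,
    white_test_p = wt$p_value,
    vif_max = vif_max,
    assumptions_met = sw$p.value > 0.05
  )
}

#' Build the method-by-outcome association matrix
#'
#' Runs the full screen-then-adjust pipeline for every (method, outcome) pair
#' of a study group: skewed outcomes are log10-transformed, pairs are admitted
#' at the bivariate screen threshold, and admitted pairs are refitted adjusted
#' for sex (coded male = 1) and -- in the eutrophic group -- for the
#' "eutrophic with excess body fat" false-negative indicator defined by
#' [classify_excess_fat()] on a configurable reference method. Per-cell
#' failures are recorded as structured reasons; the grid never aborts on a
#' cell.
#'
#' @param estimates Battery output from [evaluate_battery()].
#' @param panel Biomarker panel (derived fields computed or derivable).
#' @param subjects Subject table (for `sex`, `group`).
#' @param group `"eutrophic"`, `"overweight"`, or `NULL` for all subjects.
#' @param methods,outcomes Subsets of [bf_methods()] / [risk_outcomes()], or
#'   `"all"`.
#' @param screen_threshold,sig_threshold Strict P-value thresholds of the
#'   screen (default 0.20) and the final models (default 0.05);
#'   `screen_threshold` must exceed `sig_threshold`.
#' @param reference_method Method defining the excess-fat covariate in the
#'   eutrophic group (default `"EQ5"`).
#' @param adjust_excess_fat Include the excess-fat indicator (default: only
#'   in the eutrophic group).
#' @param robust_type Robust covariance flavour for [adjusted_regression()].
#' @return An `association_matrix`: a tibble with one row per (method,
#'   outcome) carrying the screen and adjusted-model results, the significance
#'   call, and a machine-readable `reason` for every non-reported cell
#'   (`failed_screen`, `failed_assumptions`, or `fit_error: ...`).
#' @export
build_association_matrix <- function(estimates, panel, subjects,
                                     group = NULL,
                                     methods = "all", outcomes = "all",
                                     screen_threshold = 0.20,
                                     sig_threshold = 0.05,
                                     reference_method = "EQ5",
                                     adjust_excess_fat =
                                       identical(group, "eutrophic"),
                                     robust_type = "HC3") {
  if (screen_threshold <= sig_threshold) {
    stop_adipoquant("screen_threshold must exceed sig_threshold",
                    "adipoquant_config_error")
  }
  if (identical(methods, "all")) methods <- bf_methods()
  if (identical(outcomes, "all")) outcomes <- risk_outcomes()
  if (!all(c("homa_ir", "ldl", "tc_hdl_ratio", "ldl_hdl_ratio") %in%
           names(panel))) {
    panel <- derive_panel(panel)
  }
  ids <- subjects$subject_id
  if (!is.null(group)) ids <- ids[subjects$group == group]
  sub <- subjects[subjects$subject_id %in% ids, , drop = FALSE]
  pan <- panel[match(sub$subject_id, panel$subject_id), , drop = FALSE]
  est <- estimates[estimates$subject_id %in% ids, , drop = FALSE]

  pan <- log_transform_outcomes(pan, intersect(log_outcomes(), outcomes))

  covs <- data.frame(sex = as.numeric(sub$sex == "male"))
  if (adjust_excess_fat) {
    ref <- est[est$method == reference_method, , drop = FALSE]
    covs$excess_fat <- as.numeric(
      ref$excess_fat[match(sub$subject_id, ref$subject_id)]
    )
  }
  # degenerate (constant) covariates would make the fits rank deficient
  keep <- vapply(covs, function(v) length(unique(v[!is.na(v)])) > 1, logical(1))
  covs <- covs[, keep, drop = FALSE]

  pbf_by_method <- lapply(setNames(methods, methods), function(m) {
    em <- est[est$method == m, , drop = FALSE]
    em$percent_fat[match(sub$subject_id, em$subject_id)]
  })

  method_v <- rep(methods, each = length(outcomes))
  outcome_v <- rep(outcomes, times = length(methods))
  nc <- length(method_v)
  n_v <- rep(NA_integer_, nc); screen_beta <- screen_p <- beta <-
    r_squared <- p_value <- residual_normality_p <- white_test_p <-
    vif_max <- rep(NA_real_, nc)
  admitted <- significant <- rep(FALSE, nc)
  robust_se <- assumptions_met <- rep(NA, nc)
  adjusted_for <- reason <- rep(NA_character_, nc)
  for (i in seq_len(nc)) {
    x <- pbf_by_method[[method_v[i]]]
    y <- pan[[outcome_v[i]]]
    tryCatch({
      keep <- complete.cases(x, y)
      if (sum(keep) < 10) {
        stop_adipoquant("fewer than 10 complete pairs",
                        "adipoquant_domain_error")
      }
      if (sd(x[keep]) == 0) {
        stop_adipoquant("percent fat has zero variance",
                        "adipoquant_domain_error")
      }
      sc <- screen_ols(x[keep], y[keep], screen_threshold)
      n_v[i] <- as.integer(sc$n)
      screen_beta[i] <- sc$beta
      screen_p[i] <- sc$p_value
      admitted[i] <- sc$admitted
      if (!sc$admitted) {
        reason[i] <- "failed_screen"
      } else {
        ar <- adjust_ols(y, x, covs, robust_type, 0.05)
        beta[i] <- ar$beta
        r_squared[i] <- ar$r_squared
        p_value[i] <- ar$p_value
        n_v[i] <- as.integer(ar$n)
        adjusted_for[i] <- ar$adjusted_for
        robust_se[i] <- ar$robust_se
        residual_normality_p[i] <- ar$residual_normality_p
        white_test_p[i] <- ar$white_test_p
        vif_max[i] <- ar$vif_max
        assumptions_met[i] <- ar$assumptions_met
        if (!ar$assumptions_met) {
          reason[i] <- "failed_assumptions"
        } else {
          significant[i] <- ar$p_value < sig_threshold
        }
      }
    }, error = function(e) {
      reason[i] <<- paste0("fit_error: ", conditionMessage(e))
    })
  }
  out <- tibble(
    method = method_v, outcome = outcome_v,
    log_scale = outcome_v %in% log_outcomes(),
    n = n_v, screen_beta = screen_beta, screen_p = screen_p,
    admitted = admitted, beta = beta, r_squared = r_squared,
    p_value = p_value, adjusted_for = adjusted_for, robust_se = robust_se,
    residual_normality_p = residual_normality_p,
    white_test_p = white_test_p, vif_max = vif_max,
    assumptions_met = assumptions_met, significant = significant,
    reason = reason
  )
  structure(out,
            class = c("association_matrix", class(out)),
            screen_threshold = screen_threshold,
            sig_threshold = sig_threshold,
            group = group %||% "all",
            reference_method = reference_method)
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Association matrix (group: ", attr(x, "group"), ")\n", sep = "")
  cat("  ", length(unique(x$method)), " methods x ",
      length(unique(x$outcome)), " outcomes; screen P < ",
      attr(x, "screen_threshold"), ", significance P < ",
      attr(x, "sig_threshold"), "\n", sep = "")
  cat("  admitted cells: ", sum(x$admitted), "; significant cells: ",
      sum(x$significant), "\n\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Rank body-fat methods by predicted risk-factor count
#'
#' Orders the battery methods by how many outcomes each predicts in the
#' adjusted models (assumptions met and P below the significance threshold).
#' Ties are broken deterministically: by mean adjusted R-squared over the
#' significant cells (descending), then by canonical method order.
#'
#' @param matrix An `association_matrix` from [build_association_matrix()].
#' @return Tibble with `method`, `n_significant`, `mean_r_squared`, ordered
#'   best first.
#' @export
rank_methods <- function(matrix) {
  grid <- as_tibble(matrix)
  methods <- unique(grid$method)
  per <- lapply(methods, function(m) {
    g <- grid[grid$method == m, ]
    sig <- g[g$significant, ]
    tibble(
      method = m,
      n_significant = nrow(sig),
      mean_r_squared = if (nrow(sig) > 0) mean(sig$r_squared) else 0
    )
  })
  out <- dplyr::bind_rows(per)
  canon <- match(out$method, bf_methods())
  out[order(-out$n_significant, -out$mean_r_squared, canon), ]
}

#' Render the association grid as a character table
#'
#' One row per outcome and one column per method, mirroring the familiar
#' printed layout: admitted cells with well-behaved residuals show the
#' adjusted slope (with `*` for P < 0.05), all other cells show an em dash.
#'
#' @param matrix An `association_matrix`.
#' @return Character matrix (outcomes x methods).
#' @export
format_association_grid <- function(matrix) {
  grid <- as_tibble(matrix)
  methods <- unique(grid$method)
  outcomes <- unique(grid$outcome)
  out <- matrix("—", nrow = length(outcomes), ncol = length(methods),
                dimnames = list(outcomes, methods))
  show <- grid$admitted & !is.na(grid$assumptions_met) & grid$assumptions_met
  for (i in which(show)) {
    out[grid$outcome[i], grid$method[i]] <-
      paste0(signif(grid$beta[i], 3), ifelse(grid$significant[i], "*", ""))
  }
  out
}
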