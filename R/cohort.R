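# Synthetic two-group cohort generator ---------------------------------------
#
# Emulates the statistical structure the analysis pipeline assumes: a
# eutrophic group and an overweight group whose biomarker distributions match
# per-group mean/SD targets inside observed min-max ranges, anthropometry
# driven by a latent adiposity factor (so the twelve body-fat estimates
# correlate strongly but imperfectly), derived biomarkers computed - never
# drawn - so the Friedewald and HOMA identities hold by construction, and
# optional planted percent-fat -> outcome effects for power and calibration
# experiments.

MEASURED_BIOMARKERS <- c("glucose", "insulin", "tc", "hdl", "tg",
                         "uric_acid", "sbp", "dbp")

#' Default per-group distribution targets
#'
#' Mean, SD and observed min-max range for each generated variable in each
#' group. Right-skewed triglycerides, insulin and uric acid are drawn
#' lognormal (exact mean/SD inversion) and the symmetric biomarkers Gaussian;
#' both reproduce
#' the target moments exactly in population, and their sample extremes then
#' fall naturally where observed ranges of samples this size fall. Age is the
#' exception: the study enrolled a fixed age window, a genuine eligibility
#' bound, so it is drawn from a moment-matched *truncated* normal
#' (`dist = "truncnorm"`).
#'
#' @return Nested list: group -> variable -> list(mean, sd, min, max, dist).
#' @export
default_moments <- function() {
  tgt <- function(mean, sd, min, max, dist = "normal") {
    list(mean = mean, sd = sd, min = min, max = max, dist = dist)
  }
  list(
    eutrophic = list(
      age = tgt(16.9, 1.0, 15.1, 19.0, "truncnorm"),
      weight = tgt(60.2, 6.1, 44.7, 75.9),
      height = tgt(168.4, 8.2, 149.5, 185.7),
      glucose = tgt(84.0, 6.0, 69.0, 99.0),
      tc = tgt(146.6, 26.3, 83.0, 271.0),
      hdl = tgt(48.9, 11.0, 21.0, 74.0),
      tg = tgt(63.2, 26.9, 24.0, 189.0, "lognormal"),
      uric_acid = tgt(3.7, 1.1, 1.5, 7.4, "lognormal"),
      insulin = tgt(9.1, 3.6, 2.0, 23.4, "lognormal"),
      sbp = tgt(102.9, 8.2, 82.0, 125.0),
      dbp = tgt(60.5, 7.9, 40.0, 84.0)
    ),
    overweight = list(
      age = tgt(16.7, 1.0, 15.0, 18.7, "truncnorm"),
      weight = tgt(75.7, 13.7, 57.5, 128.7),
      height = tgt(166.4, 10.3, 149.2, 191.3),
      glucose = tgt(84.7, 7.0, 71.0, 98.0),
      tc = tgt(152.0, 28.3, 87.0, 252.0),
      hdl = tgt(44.8, 10.7, 27.0, 72.0),
      tg = tgt(85.2, 53.3, 31.0, 320.0, "lognormal"),
      uric_acid = tgt(3.8, 1.2, 1.6, 7.5, "lognormal"),
      insulin = tgt(12.8, 5.6, 3.9, 27.1, "lognormal"),
      sbp = tgt(104.7, 9.3, 83.0, 125.0),
      dbp = tgt(61.1, 8.7, 43.0, 82.0)
    )
  )
}

#' Default biomarker correlation matrix
#'
#' Gaussian-copula correlations among the eight measured biomarkers: modest
#' physiological dependence (TG-insulin, glucose-insulin, TC-TG, TC-HDL,
#' SBP-DBP), zero elsewhere.
#'
#' @return 8x8 positive-definite correlation matrix over
#'   glucose, insulin, tc, hdl, tg, uric_acid, sbp, dbp.
#' @export
default_biomarker_correlation <- function() {
  v <- MEASURED_BIOMARKERS
  r <- diag(length(v))
  dimnames(r) <- list(v, v)
  set_cor <- function(a, b, val) {
    r[a, b] <<- val
    r[b, a] <<- val
  }
  # TC-HDL and TC-TG are set so the derived Friedewald LDL reproduces the
  # reported LDL dispersion (SD ~23 mg/dL) and stays well away from zero.
  set_cor("tg", "insulin", 0.30)
  set_cor("glucose", "insulin", 0.20)
  set_cor("tc", "tg", 0.35)
  set_cor("tc", "hdl", 0.35)
  set_cor("sbp", "dbp", 0.50)
  r
}

#' Specify a synthetic cohort
#'
#' @param n_eutrophic,n_overweight Group sizes (study design: 140 and 70).
#' @param female_fraction,nonwhite_fraction Demographic mix (study: 0.524
#'   women, 0.614 non-whites).
#' @param moments Per-group distribution targets (see [default_moments()]).
#' @param correlation Biomarker copula correlation (see
#'   [default_biomarker_correlation()]).
#' @param effects Optional planted percent-fat effects: a data frame with
#'   columns `method` (a [bf_methods()] id), `outcome` (a measured biomarker),
#'   `slope` and `noise_sd`. For the log-analysed outcomes (TG, insulin) the
#'   slope and noise act on the log10 analysis scale (multiplicative on the
#'   raw scale); for the remaining outcomes they are additive in the
#'   outcome's units. Percent fat is centred within group before injection so
#'   group-level moment targets are preserved.
#' @param dispersion Multiplier on all biomarker SD targets (>= 0); the
#'   min-max ranges are kept fixed.
#' @param seed Integer seed; cohorts are byte-identical given the same spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_eutrophic = 140, n_overweight = 70,
                        female_fraction = 0.524, nonwhite_fraction = 0.614,
                        moments = default_moments(),
                        correlation = default_biomarker_correlation(),
                        effects = NULL, dispersion = 1, seed = 1L) {
  if (n_eutrophic < 1 || n_overweight < 1) {
    stop_adipoquant("group sizes must be positive", "adipoquant_spec_error")
  }
  for (f in c(female_fraction, nonwhite_fraction)) {
    if (f < 0 || f > 1) {
      stop_adipoquant("fractions must lie in [0, 1]", "adipoquant_spec_error")
    }
  }
  if (dispersion < 0) {
    stop_adipoquant("dispersion must be non-negative", "adipoquant_spec_error")
  }
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values <
          -1e-8)) {
    stop_adipoquant("correlation must be symmetric positive semi-definite",
                    "adipoquant_spec_error")
  }
  for (g in names(moments)) {
    for (v in names(moments[[g]])) {
      t <- moments[[g]][[v]]
      if (t$sd < 0) {
        stop_adipoquant(paste0("negative SD target for ", g, "/", v),
                        "adipoquant_spec_error")
      }
      if (t$dist == "lognormal" && t$min <= 0) {
        stop_adipoquant(
          paste0("lognormal variable ", g, "/", v,
                 " needs a positive lower bound"),
          "adipoquant_spec_error"
        )
      }
    }
  }
  if (!is.null(effects)) {
    effects <- as.data.frame(effects)
    need <- c("method", "outcome", "slope", "noise_sd")
    if (!all(need %in% names(effects))) {
      stop_adipoquant("effects need columns method, outcome, slope, noise_sd",
                      "adipoquant_spec_error")
    }
    bad_m <- setdiff(effects$method, bf_methods())
    bad_o <- setdiff(effects$outcome, MEASURED_BIOMARKERS)
    if (length(bad_m) > 0 || length(bad_o) > 0) {
      stop_adipoquant(
        paste0("effects may only target battery methods and measured ",
               "biomarkers (derived outcomes are computed, never drawn); ",
               "offending: ", paste(c(bad_m, bad_o), collapse = ", ")),
        "adipoquant_spec_error"
      )
    }
  }
  structure(
    list(n_eutrophic = n_eutrophic, n_overweight = n_overweight,
         female_fraction = female_fraction,
         nonwhite_fraction = nonwhite_fraction,
         moments = moments, correlation = correlation,
         effects = effects, dispersion = dispersion, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Null a cohort spec's planted effects
#'
#' Returns the spec with every planted slope (and its injection noise) set to
#' zero, so that all outcomes are independent of every percent-fat estimate.
#' Used for type-I calibration experiments. Idempotent.
#'
#' @param spec A [cohort_spec()].
#' @return The nulled spec.
#' @export
plant_null <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$effects)) {
    spec$effects$slope <- 0
    spec$effects$noise_sd <- 0
  }
  spec
}

# Truncated-marginal machinery ------------------------------------------------

# Analytic mean/sd of a normal(mu, sigma) truncated to [lo, hi].
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Resolve distribution targets into underlying draw parameters. Untruncated
# Gaussian and lognormal targets invert exactly; the age window ("truncnorm")
# is solved numerically so the TRUNCATED mean/SD equal the targets.
# Infeasible targets (SD forcing mass below a positivity bound, mean outside
# the window, an SD the window cannot hold) raise a spec error. Solutions are
# memoised: the same targets recur for every replicate of an experiment.
.match_cache <- new.env(parent = emptyenv())

match_truncated <- function(mean, sd, lo, hi, dist, label) {
  key <- paste(mean, sd, lo, hi, dist, sep = "|")
  hit <- .match_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- match_truncated_impl(mean, sd, lo, hi, dist, label)
  .match_cache[[key]] <- out
  out
}

match_truncated_impl <- function(mean, sd, lo, hi, dist, label) {
  if (dist != "truncnorm" && mean <= 0) {
    stop_adipoquant(paste0("infeasible moment target for ", label,
                           ": mean must be positive"),
                    "adipoquant_spec_error")
  }
  if (sd == 0) {
    return(list(mu = if (dist == "lognormal") log(mean) else mean, sigma = 0))
  }
  if (dist == "normal") {
    # untruncated Gaussian: moments are the parameters; guard positivity
    if (pnorm(0, mean, sd) > 1e-3) {
      stop_adipoquant(
        paste0("infeasible moment target for ", label,
               ": SD places non-negligible mass below the positivity bound"),
        "adipoquant_spec_error"
      )
    }
    return(list(mu = mean, sigma = sd))
  }
  if (dist == "lognormal") {
    # exact mean/SD inversion of the lognormal
    s2 <- log(1 + (sd / mean)^2)
    return(list(mu = log(mean) - s2 / 2, sigma = sqrt(s2)))
  }
  # truncnorm: solve for the underlying parameters numerically
  if (mean < lo || mean > hi) {
    stop_adipoquant(paste0("infeasible moment target for ", label,
                           ": mean outside [min, max]"),
                    "adipoquant_spec_error")
  }
  moments_fn <- truncnorm_moments
  start <- c(mean, log(sd))
  obj <- function(p) {
    mm <- moments_fn(p[1], exp(p[2]), lo, hi)
    if (any(!is.finite(mm))) return(1e10)
    ((mm[["mean"]] - mean) / sd)^2 + ((mm[["sd"]] - sd) / sd)^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-6) {
    stop_adipoquant(paste0("infeasible moment target for ", label,
                           ": no truncated ", dist,
                           " attains the requested mean/SD inside [min, max]"),
                    "adipoquant_spec_error")
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Map standard-normal copula scores onto the target marginal.
truncated_quantile <- function(x, par, lo, hi, dist) {
  if (par$sigma == 0) {
    return(rep(if (dist == "lognormal") exp(par$mu) else par$mu, length(x)))
  }
  if (dist == "normal") return(par$mu + par$sigma * x)
  if (dist == "lognormal") return(exp(par$mu + par$sigma * x))
  pa <- pnorm((lo - par$mu) / par$sigma)
  pb <- pnorm((hi - par$mu) / par$sigma)
  par$mu + par$sigma * qnorm(pa + pnorm(x) * (pb - pa))
}

# Skinfold generation parameters: a latent adiposity factor drives all six
# folds with fold-specific loadings and noises, so the battery's estimates
# correlate strongly but imperfectly across methods.
fold_params <- data.frame(
  site = c("biceps", "triceps", "subscapular", "suprailiac",
           "midaxillary", "calf"),
  base = c(6, 9, 9, 8, 7, 10),          # male eutrophic median, mm
  female_mult = c(1.40, 1.45, 1.25, 1.35, 1.30, 1.40),
  loading = c(0.32, 0.30, 0.34, 0.38, 0.36, 0.26),
  noise = c(0.26, 0.21, 0.24, 0.28, 0.27, 0.25)
)

generate_group <- function(spec, group, n, id_offset) {
  tgt <- spec$moments[[group]]
  solve_t <- function(v, disp = 1) {
    t <- tgt[[v]]
    list(par = match_truncated(t$mean, t$sd * disp, t$min, t$max, t$dist,
                               paste0(group, "/", v)),
         t = t)
  }

  sex <- ifelse(runif(n) < spec$female_fraction, "female", "male")
  race <- ifelse(runif(n) < spec$nonwhite_fraction, "nonwhite", "white")
  z <- rnorm(n)  # latent adiposity

  draw_ind <- function(v) {
    s <- solve_t(v)
    truncated_quantile(rnorm(n), s$par, s$t$min, s$t$max, s$t$dist)
  }
  age <- draw_ind("age")
  height <- draw_ind("height")
  # weight shares the latent adiposity factor (Gaussian copula, rho = 0.72,
  # in line with the strong empirical BMI-adiposity correlation in
  # adolescents)
  sw <- solve_t("weight")
  xw <- 0.72 * z + sqrt(1 - 0.72^2) * rnorm(n)
  weight <- truncated_quantile(xw, sw$par, sw$t$min, sw$t$max, sw$t$dist)

  grp_mult <- if (group == "overweight") 1.7 else 1.0
  folds <- lapply(seq_len(nrow(fold_params)), function(i) {
    p <- fold_params[i, ]
    med <- p$base * ifelse(sex == "female", p$female_mult, 1) * grp_mult
    val <- med * exp(p$loading * z + p$noise * rnorm(n))
    pmin(pmax(val, 2), 60)
  })
  names(folds) <- fold_params$site

  resistance <- ifelse(sex == "female", 595, 520) *
    exp(0.08 * z + 0.05 * rnorm(n))
  resistance <- pmin(pmax(resistance, 330), 900)
  brachial <- ifelse(sex == "female", 26, 27) +
    (group == "overweight") * 3.5 + 1.2 * z + 0.8 * rnorm(n)
  brachial <- pmin(pmax(brachial, 17), 45)
  bia2 <- ifelse(sex == "female", 22, 13) + (group == "overweight") * 8 +
    3.5 * z + 1.8 * rnorm(n)
  bia2 <- pmin(pmax(bia2, 3), 58)

  # biomarkers: Gaussian copula, truncated moment-matched marginals
  r <- spec$correlation[MEASURED_BIOMARKERS, MEASURED_BIOMARKERS]
  ev <- eigen(r, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  zc <- matrix(rnorm(n * length(MEASURED_BIOMARKERS)), n) %*% rt
  colnames(zc) <- MEASURED_BIOMARKERS
  bio <- lapply(MEASURED_BIOMARKERS, function(v) {
    s <- solve_t(v, spec$dispersion)
    val <- truncated_quantile(zc[, v], s$par, s$t$min, s$t$max, s$t$dist)
    # floor Gaussian draws at half the observed minimum; the mass involved is
    # below 1e-3 by the feasibility guard, so moments are unaffected in
    # practice while concentrations stay physiological
    if (s$t$dist == "normal") val <- pmax(val, s$t$min / 2) else val
  })
  names(bio) <- MEASURED_BIOMARKERS

  subjects <- tibble(
    subject_id = sprintf("S%04d", id_offset + seq_len(n)),
    sex = sex, age = age, race = race, maturation = "postpubescent",
    weight = weight, height = height,
    biceps = folds$biceps, triceps = folds$triceps,
    subscapular = folds$subscapular, suprailiac = folds$suprailiac,
    midaxillary = folds$midaxillary, calf = folds$calf,
    brachial_perimeter = brachial, resistance = resistance,
    bia2_percent_fat = bia2, group = group
  )
  panel <- tibble(subject_id = subjects$subject_id)
  for (v in MEASURED_BIOMARKERS) panel[[v]] <- bio[[v]]
  list(subjects = subjects, panel = panel)
}

#' Generate a synthetic two-group cohort
#'
#' Draws subjects and biomarker panels per [cohort_spec()]. Skewed biomarkers
#' (TG, insulin) are lognormal with exact mean/SD inversion, symmetric
#' biomarkers Gaussian, both matching the target moments exactly in
#' population; age respects the study's enrollment window via a
#' moment-matched truncated normal. Dependence enters through a Gaussian
#' copula over the measured biomarkers. A
#' latent adiposity factor links weight, the six skinfolds, resistance, the
#' brachial perimeter and the direct vertical-device reading. Derived
#' biomarkers (LDL, HOMA-IR, lipid ratios) are computed from the drawn
#' measured fields after any planted effects are injected, so the Friedewald
#' and HOMA identities hold by construction.
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (one row per adolescent) and `panels` (the
#'   derived biomarker panel).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_eutrophic = 30, n_overweight = 15,
#'                                       seed = 7))
#' nrow(cohort$subjects)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  g1 <- generate_group(spec, "eutrophic", spec$n_eutrophic, 0L)
  g2 <- generate_group(spec, "overweight", spec$n_overweight,
                       spec$n_eutrophic)
  subjects <- dplyr::bind_rows(g1$subjects, g2$subjects)
  panel <- dplyr::bind_rows(g1$panel, g2$panel)

  if (!is.null(spec$effects) && nrow(spec$effects) > 0) {
    est <- evaluate_battery(subjects,
                            methods = unique(spec$effects$method))
    for (i in seq_len(nrow(spec$effects))) {
      ef <- spec$effects[i, ]
      em <- est[est$method == ef$method, ]
      pbf <- em$percent_fat[match(panel$subject_id, em$subject_id)]
      # centre within group so group-level moment targets are preserved
      pbf_c <- stats::ave(pbf, subjects$group,
                          FUN = function(v) v - mean(v, na.rm = TRUE))
      pbf_c[is.na(pbf_c)] <- 0
      shift <- ef$slope * pbf_c + rnorm(nrow(panel), 0, ef$noise_sd)
      if (ef$outcome %in% log_outcomes()) {
        panel[[ef$outcome]] <- panel[[ef$outcome]] * 10^shift
      } else {
        panel[[ef$outcome]] <- panel[[ef$outcome]] + shift
      }
    }
  }
  list(subjects = subjects, panels = derive_panel(panel))
}
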