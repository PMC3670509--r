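# Package-level plumbing: CSV I/O, run configuration, end-to-end driver ------

#' Read and validate a subject CSV
#'
#' Expects one row per subject with columns named as in the subject schema
#' (see [validate_subjects()]); empty cells become missing fields. A column
#' mapping allows foreign headers: either a named character vector
#' (`c(schema_name = "file_header", ...)`) or the path to a YAML file with the
#' same structure.
#'
#' @param path CSV file path.
#' @param mapping Optional column mapping (named character vector or YAML
#'   path).
#' @param decimal_comma Read `","` as the decimal separator (source data from
#'   locales that use it); the package always writes `"."`.
#' @return Validated subject tibble. Hard schema or row-level violations
#'   raise an error naming the rows and fields involved.
#' @export
read_subjects <- function(path, mapping = NULL, decimal_comma = FALSE) {
  if (!file.exists(path)) {
    stop_adipoquant(paste0("file not found: ", path), "adipoquant_io_error")
  }
  loc <- readr::locale(decimal_mark = if (decimal_comma) "," else ".",
                       grouping_mark = if (decimal_comma) "." else ",")
  df <- readr::read_csv(path, locale = loc, show_col_types = FALSE,
                        progress = FALSE)
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1 && is.null(names(mapping))) {
      mapping <- unlist(yaml::read_yaml(mapping))
    }
    for (schema_name in names(mapping)) {
      hdr <- mapping[[schema_name]]
      if (!hdr %in% names(df)) {
        stop_adipoquant(paste0("mapped column not in file: ", hdr),
                        "adipoquant_schema_error")
      }
      names(df)[names(df) == hdr] <- schema_name
    }
  }
  extra <- setdiff(names(df), SUBJECT_COLUMNS)
  if (length(extra) > 0) df <- df[, setdiff(names(df), extra), drop = FALSE]
  if ("subject_id" %in% names(df)) {
    df$subject_id <- as.character(df$subject_id)
  }
  assert_valid_subjects(df)
  as_tibble(df)
}

#' Configuration for an end-to-end run
#'
#' @param input Path to a subject CSV, or `NULL` to simulate a cohort from
#'   `cohort` (defaults to the calibrated two-group design).
#' @param cohort A [cohort_spec()] used when `input` is `NULL`.
#' @param panel_input Path to a measured-biomarker CSV when `input` is given;
#'   columns `subject_id` plus the measured biomarkers.
#' @param out_dir Output directory for all artifacts.
#' @param methods Battery method selection (`"all"` or ids).
#' @param screen_threshold,final_threshold Screen and significance P
#'   thresholds; both in (0, 1) with `screen_threshold > final_threshold`.
#' @param robust_type Robust covariance flavour.
#' @param reference_method Excess-fat reference method for the eutrophic-group
#'   adjustment.
#' @param excess_fat_thresholds Passed to [classify_excess_fat()].
#' @param cutoffs Risk-flag cutoffs ([risk_cutoffs()]).
#' @param seed Seed for simulation.
#' @param mapping,decimal_comma Passed to [read_subjects()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, cohort = cohort_spec(seed = seed),
                       panel_input = NULL,
                       out_dir = tempfile("adipoquant_run_"),
                       methods = "all",
                       screen_threshold = 0.20, final_threshold = 0.05,
                       robust_type = "HC3", reference_method = "EQ5",
                       excess_fat_thresholds = c(male = 20, female = 25),
                       cutoffs = risk_cutoffs(), seed = 1L,
                       mapping = NULL, decimal_comma = FALSE) {
  for (th in c(screen_threshold, final_threshold)) {
    if (!is.finite(th) || th <= 0 || th >= 1) {
      stop_adipoquant("thresholds must lie strictly between 0 and 1",
                      "adipoquant_config_error")
    }
  }
  if (screen_threshold <= final_threshold) {
    stop_adipoquant("screen_threshold must exceed final_threshold",
                    "adipoquant_config_error")
  }
  if (!reference_method %in% bf_methods()) {
    stop_adipoquant("unknown reference_method", "adipoquant_config_error")
  }
  cfg <- list(input = input, cohort = cohort, panel_input = panel_input,
              out_dir = out_dir, methods = methods,
              screen_threshold = screen_threshold,
              final_threshold = final_threshold, robust_type = robust_type,
              reference_method = reference_method,
              excess_fat_thresholds = excess_fat_thresholds,
              cutoffs = cutoffs, seed = as.integer(seed),
              mapping = mapping, decimal_comma = decimal_comma)
  structure(cfg, class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) a cohort, evaluate the body-fat battery, derive the
#' biomarker panel and risk flags, build the association matrix per study
#' group, rank the methods, and write every artifact plus a Markdown report
#' with a provenance block (config hash, seed, package version) to
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects, the output paths and
#'   `status = 0`. Any stage failure raises a stage-tagged error.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_adipoquant(paste0("[", stage, "] ", conditionMessage(e)),
                      "adipoquant_stage_error")
    })
  }

  dat <- with_stage("input", {
    if (is.null(config$input)) {
      stage_log("input", "simulating cohort (seed ", config$cohort$seed, ")")
      generate_cohort(config$cohort)
    } else {
      stage_log("input", "reading ", config$input)
      subjects <- read_subjects(config$input, config$mapping,
                                config$decimal_comma)
      if (is.null(config$panel_input)) {
        stop_adipoquant("panel_input is required when input is a file",
                        "adipoquant_config_error")
      }
      panel <- readr::read_csv(config$panel_input, show_col_types = FALSE,
                               progress = FALSE)
      panel$subject_id <- as.character(panel$subject_id)
      list(subjects = subjects, panels = derive_panel(panel))
    }
  })

  estimates <- with_stage("battery", {
    stage_log("battery", "evaluating body-fat methods")
    evaluate_battery(dat$subjects, methods = config$methods,
                     excess_fat_thresholds = config$excess_fat_thresholds)
  })

  flags <- with_stage("biomarkers", {
    stage_log("biomarkers", "risk flags")
    risk_flags(dat$panels, dat$subjects$sex, config$cutoffs)
  })

  groups <- intersect(c("eutrophic", "overweight"), unique(dat$subjects$group))
  matrices <- with_stage("associate", {
    lapply(setNames(groups, groups), function(g) {
      stage_log("associate", "group ", g)
      build_association_matrix(
        estimates, dat$panels, dat$subjects, group = g,
        methods = config$methods,
        screen_threshold = config$screen_threshold,
        sig_threshold = config$final_threshold,
        reference_method = config$reference_method,
        robust_type = config$robust_type
      )
    })
  })
  rankings <- lapply(matrices, rank_methods)

  paths <- with_stage("write", {
    p <- list(
      subjects = file.path(config$out_dir, "subjects.csv"),
      panel = file.path(config$out_dir, "panel.csv"),
      estimates = file.path(config$out_dir, "estimates.csv"),
      flags = file.path(config$out_dir, "flags.csv"),
      report = file.path(config$out_dir, "report.md")
    )
    readr::write_csv(dat$subjects, p$subjects)
    readr::write_csv(dat$panels, p$panel)
    readr::write_csv(estimates, p$estimates)
    readr::write_csv(flags, p$flags)
    for (g in groups) {
      p[[paste0("grid_", g)]] <-
        file.path(config$out_dir, paste0("association_", g, ".csv"))
      readr::write_csv(as_tibble(matrices[[g]]), p[[paste0("grid_", g)]])
      p[[paste0("ranking_", g)]] <-
        file.path(config$out_dir, paste0("ranking_", g, ".csv"))
      readr::write_csv(rankings[[g]], p[[paste0("ranking_", g)]])
    }
    writeLines(render_report(config, dat, flags, matrices, rankings),
               p$report)
    p
  })
  stage_log("done", "artifacts in ", config$out_dir)
  invisible(list(status = 0, subjects = dat$subjects, panels = dat$panels,
                 estimates = estimates, flags = flags, matrices = matrices,
                 rankings = rankings, paths = paths))
}

render_report <- function(config, dat, flags, matrices, rankings) {
  cfg_hash <- hash(config[setdiff(names(config), "out_dir")])
  lines <- c(
    "# Body-fat battery and cardiometabolic risk report", "",
    "## Provenance", "",
    paste0("- config hash: `", cfg_hash, "`"),
    paste0("- seed: ", config$seed),
    paste0("- adipoquant version: ",
           as.character(utils::packageVersion("adipoquant"))),
    "",
    "## Cohort", "",
    paste0("- subjects: ", nrow(dat$subjects),
           " (", sum(dat$subjects$group == "eutrophic"), " eutrophic, ",
           sum(dat$subjects$group == "overweight"), " overweight)"),
    paste0("- with at least one risk flag: ",
           round_half_up(100 * mean(flags$any_risk), 1), "%"),
    ""
  )
  for (g in names(matrices)) {
    rk <- rankings[[g]]
    lines <- c(
      lines,
      paste0("## Group: ", g), "",
      "Method ranking by number of predicted risk factors:", "",
      paste0("| method | n significant | mean adjusted R2 |"),
      paste0("|---|---|---|"),
      sprintf("| %s | %d | %.3f |", rk$method, rk$n_significant,
              rk$mean_r_squared),
      "",
      "Adjusted-model grid (slope; `*` P < 0.05; `—` screened out or",
      "assumptions not met):", ""
    )
    gr <- format_association_grid(matrices[[g]])
    hdr <- paste0("| outcome | ", paste(colnames(gr), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(gr) + 1), collapse = "|"), "|")
    body <- vapply(rownames(gr), function(o) {
      paste0("| ", o, " | ", paste(gr[o, ], collapse = " | "), " |")
    }, character(1))
    lines <- c(lines, hdr, sep, body, "")
  }
  lines
}
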