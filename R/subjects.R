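# Subject records -------------------------------------------------------------

SKINFOLD_SITES <- c("biceps", "triceps", "subscapular", "suprailiac",
                    "midaxillary", "calf")

SUBJECT_COLUMNS <- c(
  "subject_id", "sex", "age", "race", "maturation", "weight", "height",
  SKINFOLD_SITES, "brachial_perimeter", "resistance", "bia2_percent_fat",
  "group"
)

# Columns that must exist (possibly with missing cells); bia2_percent_fat and
# some measurements may be absent entirely and the battery then skips the
# methods that need them.
SUBJECT_REQUIRED <- c("subject_id", "sex", "age", "weight", "height", "group")

#' Validate a table of subject records
#'
#' Checks one-row-per-adolescent anthropometry records against the schema used
#' throughout the package: positive weight, height, skinfolds and resistance;
#' recognised factor levels for `sex` (`male`/`female`), `race`
#' (`white`/`nonwhite`), `maturation` (`prepubescent`/`pubescent`/
#' `postpubescent`) and `group` (`eutrophic`/`overweight`); and a soft age
#' range of 10--25 years (the prediction equations were developed for
#' adolescents; ages outside raise a warning, not an error).
#'
#' The nutritional-status `group` label is an input classification and is
#' never recomputed here.
#'
#' @param subjects A data frame of subject records.
#' @return A tibble of validation issues with columns `row`, `field`,
#'   `severity` (`"error"` or `"warning"`) and `message`; zero rows when the
#'   table is clean.
#' @export
validate_subjects <- function(subjects) {
  if (!is.data.frame(subjects)) {
    stop_adipoquant("`subjects` must be a data frame", "adipoquant_schema_error")
  }
  missing_cols <- setdiff(SUBJECT_REQUIRED, names(subjects))
  if (length(missing_cols) > 0) {
    stop_adipoquant(
      paste0("subject table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "adipoquant_schema_error"
    )
  }

  issues <- list()
  note <- function(rows, field, severity, message) {
    if (length(rows) > 0) {
      issues[[length(issues) + 1]] <<-
        tibble(row = rows, field = field, severity = severity,
               message = message)
    }
  }

  bad_level <- function(field, levels) {
    if (!field %in% names(subjects)) return()
    x <- subjects[[field]]
    rows <- which(!is.na(x) & !x %in% levels)
    note(rows, field, "error",
         paste0("must be one of: ", paste(levels, collapse = ", ")))
  }
  bad_level("sex", c("male", "female"))
  bad_level("race", c("white", "nonwhite"))
  bad_level("maturation", c("prepubescent", "pubescent", "postpubescent"))
  bad_level("group", c("eutrophic", "overweight"))

  positive <- function(field) {
    if (!field %in% names(subjects)) return()
    x <- subjects[[field]]
    note(which(!is.na(x) & x <= 0), field, "error", "must be positive")
  }
  for (f in c("weight", "height", SKINFOLD_SITES, "brachial_perimeter",
              "resistance")) {
    positive(f)
  }

  if ("age" %in% names(subjects)) {
    a <- subjects$age
    note(which(!is.na(a) & (a < 10 | a > 25)), "age", "warning",
         "outside 10-25 years; prediction equations are defined for adolescents")
  }

  out <- if (length(issues) == 0) {
    tibble(row = integer(), field = character(), severity = character(),
           message = character())
  } else {
    dplyr::bind_rows(issues)
  }
  if (any(out$severity == "warning")) {
    w <- out[out$severity == "warning", ]
    warn(paste0("subject validation warnings: ",
                paste0("row ", w$row, " ", w$field, " (", w$message, ")",
                       collapse = "; ")))
  }
  out
}

# Internal: error if the issue table has hard violations.
assert_valid_subjects <- function(subjects) {
  issues <- validate_subjects(subjects)
  errs <- issues[issues$severity == "error", ]
  if (nrow(errs) > 0) {
    stop_adipoquant(
      paste0("invalid subject record(s): ",
             paste0("row ", errs$row, ", field `", errs$field, "`: ",
                    errs$message, collapse = "; ")),
      "adipoquant_validation_error"
    )
  }
  invisible(subjects)
}
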