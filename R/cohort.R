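#' Construct and validate a subject-level cohort
#'
#' A cohort is a data frame with one row per subject, a binary treatment
#' column, a binary outcome column, numeric covariate columns, and zero or
#' more covariates designated as Introduced Variables. Validation is
#' strict: treatment and outcome must be coded exactly 0/1, no missing
#' values are allowed in used columns, and both arms must meet a minimum
#' size.
#'
#' @param data A data frame.
#' @param treatment,outcome Names of the treatment and outcome columns.
#' @param iv_columns Character vector naming the covariates designated as
#'   Introduced Variables (may be empty; can also be set later through the
#'   model specification).
#' @param min_arm_size Minimum number of subjects required per arm.
#' @return The validated data frame with class `acce_cohort` and attributes
#'   `treatment`, `outcome`, `iv_columns`.
#' @export
as_cohort <- function(data, treatment = "treatment", outcome = "outcome",
                      iv_columns = character(), min_arm_size = 2L) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame")
  missing_cols <- setdiff(c(treatment, outcome, iv_columns), names(data))
  if (length(missing_cols)) {
    abort_input(paste0("column(s) not found in data: ",
                       paste(missing_cols, collapse = ", ")))
  }
  data <- as.data.frame(data)
  for (col in c(treatment, outcome)) {
    v <- data[[col]]
    if (is.logical(v)) v <- as.integer(v)
    if (anyNA(v)) {
      abort_input(sprintf("column '%s' contains %d missing value(s)",
                          col, sum(is.na(v))))
    }
    bad <- !(v %in% c(0, 1))
    if (any(bad)) {
      abort_input(sprintf(
        "column '%s' must be coded 0/1; found %d offending value(s): %s",
        col, sum(bad),
        paste(utils::head(unique(v[bad]), 5), collapse = ", ")
      ))
    }
    data[[col]] <- as.integer(v)
  }
  covariate_cols <- setdiff(names(data), c(treatment, outcome))
  for (col in covariate_cols) {
    if (!is.numeric(data[[col]]) && !is.logical(data[[col]])) {
      abort_input(sprintf("covariate column '%s' must be numeric", col))
    }
    if (anyNA(data[[col]])) {
      abort_input(sprintf("covariate column '%s' contains %d missing value(s)",
                          col, sum(is.na(data[[col]]))))
    }
  }
  n_treated <- sum(data[[treatment]] == 1L)
  n_comparison <- sum(data[[treatment]] == 0L)
  if (n_treated < min_arm_size || n_comparison < min_arm_size) {
    abort_input(sprintf(
      "each arm needs at least %d subjects (found %d treated, %d comparison)",
      min_arm_size, n_treated, n_comparison
    ))
  }
  structure(data,
            treatment = treatment, outcome = outcome,
            iv_columns = iv_columns,
            class = c("acce_cohort", "data.frame"))
}

cohort_treatment <- function(cohort) cohort[[attr(cohort, "treatment")]]
cohort_outcome <- function(cohort) cohort[[attr(cohort, "outcome")]]

#' @export
print.acce_cohort <- function(x, ...) {
  tr <- cohort_treatment(x)
  cat(sprintf(
    "Cohort: %d subjects (%d treated, %d comparison), %d event(s), %d covariate column(s)\n",
    nrow(x), sum(tr == 1L), sum(tr == 0L), sum(cohort_outcome(x)),
    ncol(x) - 2L
  ))
  if (length(attr(x, "iv_columns"))) {
    cat("  Introduced Variable(s):",
        paste(attr(x, "iv_columns"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Reads a header CSV, applies a column mapping, drops rows with missing
#' values in the mapped columns (reporting the count), and validates the
#' result with [as_cohort()].
#'
#' @param path Path to a CSV file with a header row.
#' @param treatment,outcome Column names in the file holding the 0/1
#'   treatment and outcome indicators.
#' @param covariates Optional character vector restricting which covariate
#'   columns are kept; default keeps all remaining columns.
#' @param iv_columns Covariates designated as Introduced Variables.
#' @param min_arm_size Passed to [as_cohort()].
#' @return An `acce_cohort`.
#' @export
read_cohort <- function(path, treatment = "treatment", outcome = "outcome",
                        covariates = NULL, iv_columns = character(),
                        min_arm_size = 2L) {
  if (!file.exists(path)) abort_input(paste0("cohort file not found: ", path))
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  keep <- c(treatment, outcome,
            if (is.null(covariates)) setdiff(names(data), c(treatment, outcome))
            else covariates)
  missing_cols <- setdiff(keep, names(data))
  if (length(missing_cols)) {
    abort_input(paste0("column(s) not found in ", path, ": ",
                       paste(missing_cols, collapse = ", ")))
  }
  data <- data[, keep, drop = FALSE]
  complete <- stats::complete.cases(data)
  if (!all(complete)) {
    message(sprintf("read_cohort: dropped %d of %d rows with missing values",
                    sum(!complete), nrow(data)))
    data <- data[complete, , drop = FALSE]
  }
  if (!nrow(data)) abort_input("no complete rows remain after validation")
  as_cohort(data, treatment = treatment, outcome = outcome,
            iv_columns = iv_columns, min_arm_size = min_arm_size)
}

#' Write a cohort to CSV
#'
#' @param cohort An `acce_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
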