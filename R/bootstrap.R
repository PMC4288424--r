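#' Case-resampling bootstrap interval for the unconfounded effect
#'
#' Resamples whole subjects with replacement and re-runs the entire
#' pipeline — both propensity fits, both stratified effect estimates, the
#' Introduced Variable outcome coefficients, the Bross terms and the
#' summary equation — on every replicate, returning a percentile interval
#' for the unconfounded treatment effect. Replicates on which the
#' back-extrapolation fails (e.g. the resampled Model 2 R^2 does not
#' exceed Model 1's) are dropped and counted; more than 20% failures is an
#' error. The interval is deterministic under a fixed seed.
#'
#' @param cohort An `acce_cohort`.
#' @param spec A [nested_model_spec()].
#' @param B Number of bootstrap replicates (>= 2).
#' @param level Interval level in (0, 1); default 0.95.
#' @param seed Integer seed.
#' @param stratified_by_arm If `TRUE`, resample within each treatment arm
#'   so arm sizes are preserved.
#' @return An object of class `acce_boot`: `replicates`, `point`,
#'   `ci_low`, `ci_high`, `level`, `failed_replicates`, `estimates`,
#'   `warnings`.
#' @export
bootstrap_ci <- function(cohort, spec, B = 500L, level = 0.95, seed = 1L,
                         stratified_by_arm = FALSE) {
  if (!inherits(cohort, "acce_cohort")) abort_input("`cohort` must be an acce_cohort")
  if (!inherits(spec, "nested_model_spec")) abort_input("`spec` must be a nested_model_spec")
  B <- as.integer(B)
  if (is.na(B) || B < 2L) abort_input("`B` must be an integer >= 2")
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort_input("`level` must lie strictly between 0 and 1")
  }
  point <- suppressWarnings(acce_cohort(cohort, spec))$unconfounded_tee

  set.seed(as.integer(seed))
  n <- nrow(cohort)
  tr <- cohort_treatment(cohort)
  idx_treated <- which(tr == 1L)
  idx_comparison <- which(tr == 0L)
  failure_classes <- character()
  estimates <- vapply(seq_len(B), function(b) {
    idx <- if (stratified_by_arm) {
      c(sample(idx_treated, length(idx_treated), replace = TRUE),
        sample(idx_comparison, length(idx_comparison), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    boot_data <- as.data.frame(cohort)[idx, , drop = FALSE]
    tryCatch({
      boot_cohort <- as_cohort(boot_data,
                               treatment = attr(cohort, "treatment"),
                               outcome = attr(cohort, "outcome"),
                               iv_columns = attr(cohort, "iv_columns"))
      suppressWarnings(acce_cohort(boot_cohort, spec))$unconfounded_tee
    }, acce_error = function(e) {
      failure_classes <<- c(failure_classes, class(e)[1])
      NA_real_
    })
  }, numeric(1))

  failed <- sum(is.na(estimates))
  if (failed > 0.20 * B) {
    breakdown <- paste(sprintf("%s: %d", names(table(failure_classes)),
                               as.integer(table(failure_classes))),
                       collapse = "; ")
    abort_inference(sprintf(
      "bootstrap failed on %d of %d replicates (> 20%%); breakdown: %s",
      failed, B, breakdown
    ))
  }
  ok <- estimates[!is.na(estimates)]
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(ok, c(alpha, 1 - alpha), type = 7))
  warnings <- character()
  if (point < ci[1] || point > ci[2]) {
    warnings <- c(warnings,
                  "point estimate falls outside the percentile interval (skewed bootstrap distribution)")
  }
  structure(
    list(replicates = B, point = point,
         ci_low = ci[1], ci_high = ci[2], level = level,
         failed_replicates = failed,
         failure_breakdown = if (failed) table(failure_classes) else NULL,
         estimates = estimates,
         warnings = warnings),
    class = "acce_boot"
  )
}

#' @export
print.acce_boot <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Bootstrap (%d replicates, %d failed): unconfounded beta %.*f, %.0f%% CI [%.*f, %.*f]\n",
    x$replicates, x$failed_replicates, digits, x$point, 100 * x$level,
    digits, x$ci_low, digits, x$ci_high
  ))
  cat(sprintf("  on the risk-ratio scale: %.*f [%.*f, %.*f]\n",
              digits, exp(x$point), digits, exp(x$ci_low), digits, exp(x$ci_high)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
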