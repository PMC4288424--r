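#' Specification of the nested propensity-score models
#'
#' Model 1 uses `model1_covariates`; Model 2 uses the same covariates plus
#' the `introduced_variables`. An optional `withheld_marker` is a measured
#' covariate deliberately excluded from both models so that the growth of
#' its between-arm imbalance can serve as an internal, empirical index of
#' confounding amplification (see [internal_marker_amplification()]).
#'
#' @param model1_covariates Covariate names for Model 1.
#' @param introduced_variables Covariate names added to form Model 2;
#'   must be disjoint from `model1_covariates`.
#' @param n_strata Number of propensity-score quantile strata used for
#'   effect estimation (default 10).
#' @param withheld_marker Optional covariate name excluded from both
#'   models.
#' @param m1_balance How the Introduced Variable's Model 1 balance entering
#'   the Bross terms is measured: within Model 1 propensity strata
#'   (`"stratified"`, default — the balance Model 1 actually achieves) or
#'   from the raw arms (`"raw"`).
#' @param min_increment Minimum between-model amplification increment
#'   accepted for quantitative back-extrapolation (default 0.01). Because
#'   Model 2 nests Model 1, the in-sample R^2 difference is never negative;
#'   an increment this small means the Introduced Variable barely predicts
#'   exposure and dividing by it would amplify sampling noise without
#'   bound, so the pipeline treats it as extrapolation-invalid.
#' @param known_instrument If `TRUE`, the Introduced Variable(s) are
#'   declared true instruments (no outcome association except through
#'   treatment), and the pipeline skips the outcome-coefficient and Bross
#'   adjustments entirely: with a known instrument the back-extrapolation
#'   alone suffices. Estimating a coefficient that is truly zero is not
#'   harmless — within-arm outcome regressions condition on treatment,
#'   which induces a collider association between the Introduced Variable
#'   and unmeasured confounders, and the resulting spurious adjustment is
#'   leveraged by the Bross terms. Default `FALSE`.
#' @return An object of class `nested_model_spec`.
#' @export
nested_model_spec <- function(model1_covariates, introduced_variables,
                              n_strata = 10L, withheld_marker = NULL,
                              m1_balance = c("stratified", "raw"),
                              min_increment = 0.01,
                              known_instrument = FALSE) {
  m1_balance <- match.arg(m1_balance)
  if (!is.character(model1_covariates) || !length(model1_covariates)) {
    abort_input("`model1_covariates` must be a non-empty character vector")
  }
  if (!is.character(introduced_variables)) {
    abort_input("`introduced_variables` must be a character vector (may be empty for diagnostics)")
  }
  overlap <- intersect(model1_covariates, introduced_variables)
  if (length(overlap)) {
    abort_input(paste0("introduced variable(s) already in Model 1: ",
                       paste(overlap, collapse = ", ")))
  }
  if (!is.null(withheld_marker)) {
    if (withheld_marker %in% c(model1_covariates, introduced_variables)) {
      abort_input("`withheld_marker` must be excluded from both models")
    }
  }
  n_strata <- as.integer(n_strata)
  if (is.na(n_strata) || n_strata < 1L) abort_input("`n_strata` must be >= 1")
  structure(
    list(model1_covariates = model1_covariates,
         introduced_variables = introduced_variables,
         n_strata = n_strata,
         withheld_marker = withheld_marker,
         m1_balance = m1_balance,
         min_increment = min_increment,
         known_instrument = isTRUE(known_instrument)),
    class = "nested_model_spec"
  )
}

#' @export
print.nested_model_spec <- function(x, ...) {
  cat("Nested propensity-score model specification\n")
  cat("  Model 1:", paste(x$model1_covariates, collapse = " + "), "\n")
  cat("  Introduced Variable(s):",
      paste(x$introduced_variables, collapse = " + "), "\n")
  cat(sprintf("  Strata: %d; Model 1 balance: %s%s\n", x$n_strata, x$m1_balance,
              if (x$known_instrument) "; Introduced Variable(s) declared instruments" else ""))
  if (!is.null(x$withheld_marker)) {
    cat("  Withheld internal marker:", x$withheld_marker, "\n")
  }
  invisible(x)
}

#' Fit a linear-probability propensity model
#'
#' Ordinary least squares of the 0/1 treatment indicator on the named
#' covariates (with intercept). The linear-probability form is used because
#' the proportionality of confounding amplification to `1/(1 - R^2)` has
#' been demonstrated for the linear R^2 of exposure prediction; no
#' analogous calibration exists for logistic pseudo-R^2 or c statistics.
#'
#' @param cohort An `acce_cohort`.
#' @param covariate_names Covariates to include.
#' @return An object of class `acce_ps_fit`: `coefficients`, per-subject
#'   fitted `scores`, `r2`, `covariates`, `n`.
#' @export
fit_linear_ps <- function(cohort, covariate_names) {
  if (!inherits(cohort, "acce_cohort")) abort_input("`cohort` must be an acce_cohort")
  if (!is.character(covariate_names) || !length(covariate_names)) {
    abort_input("`covariate_names` must be a non-empty character vector")
  }
  missing_cols <- setdiff(covariate_names, names(cohort))
  if (length(missing_cols)) {
    abort_input(paste0("covariate(s) not in cohort: ",
                       paste(missing_cols, collapse = ", ")))
  }
  y <- cohort_treatment(cohort)
  x <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(cohort)[, covariate_names, drop = FALSE]))
  fit <- stats::lm.fit(x, y)
  if (fit$rank < ncol(x)) {
    aliased <- colnames(x)[is.na(fit$coefficients)]
    abort_input(paste0(
      "singular propensity design: collinear column(s) ",
      paste(aliased, collapse = ", ")
    ))
  }
  scores <- as.numeric(x %*% fit$coefficients)
  tss <- sum((y - mean(y))^2)
  rss <- sum(fit$residuals^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  if (r2 >= 1 - 1e-12) {
    abort_extrapolation("propensity R^2 is 1 (perfect separation): amplification undefined")
  }
  structure(
    list(coefficients = fit$coefficients, scores = scores, r2 = r2,
         covariates = covariate_names, n = length(y)),
    class = "acce_ps_fit"
  )
}

#' @export
print.acce_ps_fit <- function(x, ...) {
  cat(sprintf("Linear-probability propensity fit: %d subjects, %d covariate(s), R^2 = %.4f\n",
              x$n, length(x$covariates), x$r2))
  invisible(x)
}

# Deterministic quantile strata: rank with stable first-occurrence
# tie-breaking, then equal-count bins. Seed-free by construction.
ps_strata <- function(scores, n_strata) {
  n <- length(scores)
  n_strata <- min(as.integer(n_strata), n)
  if (diff(range(scores)) < 1e-12) return(rep(1L, n)) # constant score: one stratum
  r <- rank(scores, ties.method = "first")
  as.integer(ceiling(r * n_strata / n))
}

#' Treatment effect by propensity-score stratification
#'
#' Subjects are binned into quantile strata of the propensity score and the
#' per-stratum risk ratios are pooled with Mantel-Haenszel weights. Strata
#' lacking subjects in either arm are dropped with a warning. The pooled
#' estimate is returned on the log-risk-ratio (beta) scale. With
#' `n_strata = 1` (or `fit = NULL`) the result is exactly the crude log
#' risk ratio.
#'
#' @param cohort An `acce_cohort`.
#' @param fit An `acce_ps_fit`, or `NULL` for a single crude stratum.
#' @param n_strata Number of quantile strata (default 10).
#' @return An object of class `acce_tee`: `beta`, `rr`, `n_strata_used`,
#'   `n_strata_dropped`.
#' @export
estimate_tee_stratified <- function(cohort, fit = NULL, n_strata = 10L) {
  if (!inherits(cohort, "acce_cohort")) abort_input("`cohort` must be an acce_cohort")
  tr <- cohort_treatment(cohort)
  y <- cohort_outcome(cohort)
  strata <- if (is.null(fit) || n_strata <= 1L) {
    rep(1L, length(tr))
  } else {
    if (!inherits(fit, "acce_ps_fit")) abort_input("`fit` must be an acce_ps_fit")
    ps_strata(fit$scores, n_strata)
  }
  # per-stratum 2x2 margins
  n1 <- rowsum(as.numeric(tr == 1L), strata)[, 1]
  n0 <- rowsum(as.numeric(tr == 0L), strata)[, 1]
  a <- rowsum(as.numeric(tr == 1L & y == 1L), strata)[, 1]
  b <- rowsum(as.numeric(tr == 0L & y == 1L), strata)[, 1]
  usable <- n1 > 0 & n0 > 0
  dropped <- sum(!usable)
  if (dropped > 0) {
    warning(sprintf("dropped %d stratum/strata lacking subjects in one arm", dropped),
            call. = FALSE)
  }
  if (!any(usable)) abort_estimation("all propensity-score strata are degenerate")
  t_tot <- n1[usable] + n0[usable]
  num <- sum(a[usable] * n0[usable] / t_tot)
  den <- sum(b[usable] * n1[usable] / t_tot)
  if (num <= 0 || den <= 0) {
    abort_estimation("Mantel-Haenszel risk ratio undefined: an arm has no events in any usable stratum")
  }
  rr <- num / den
  structure(
    list(beta = log(rr), rr = rr,
         n_strata_used = sum(usable), n_strata_dropped = dropped),
    class = "acce_tee"
  )
}

#' @export
print.acce_tee <- function(x, ...) {
  cat(sprintf("Stratified treatment effect: RR %.4f (beta %.6f), %d stratum/strata used",
              x$rr, x$beta, x$n_strata_used))
  if (x$n_strata_dropped > 0) cat(sprintf(" (%d dropped)", x$n_strata_dropped))
  cat("\n")
  invisible(x)
}

# log-risk outcome regression for one arm (or pooled); returns the named
# coefficient on the log-RR scale plus the method used.
log_risk_coefficient <- function(data, outcome, terms, target) {
  form <- stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  y <- data[[outcome]]
  fit <- tryCatch({
    mm <- stats::model.matrix(form, data)
    start <- c(log(max(mean(y), 1e-6)), rep(0, ncol(mm) - 1L))
    g <- suppressWarnings(stats::glm(form, data = data,
                                     family = stats::binomial(link = "log"),
                                     start = start))
    if (!g$converged) NULL else g
  }, error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)[target]
    if (!is.na(co)) return(list(coef = unname(co), method = "log_binomial"))
  }
  # linear-risk fallback: slope on the risk scale, delta-method conversion
  # to log-RR at the mean risk
  lfit <- stats::lm(form, data = data)
  co <- stats::coef(lfit)[target]
  if (is.na(co)) {
    abort_estimation(sprintf("coefficient for '%s' inestimable in outcome regression", target))
  }
  mu <- mean(stats::fitted(lfit))
  if (mu <= 0) abort_estimation("mean fitted risk non-positive in linear-risk fallback")
  list(coef = unname(co) / mu, method = "linear_risk_delta")
}

#' Introduced Variable-outcome coefficient via within-arm regressions
#'
#' Fits a log-link risk regression of the outcome on the Introduced
#' Variable plus the other propensity-score covariates separately within
#' each treatment arm, and returns the arm-size-weighted average of the two
#' coefficients on the log-risk-ratio scale. Within-arm regressions avoid
#' the strong Introduced Variable-treatment correlation; when the variable
#' is constant within an arm the function falls back, with a warning, to a
#' single pooled regression that includes the treatment indicator. If a
#' log-binomial fit fails to converge, a linear-risk fit with delta-method
#' conversion to log-RR is used and flagged.
#'
#' @param cohort An `acce_cohort`.
#' @param iv_name The Introduced Variable.
#' @param other_covariates Other covariates to adjust for (typically the
#'   Model 1 set).
#' @return The pooled coefficient (log-RR per unit of the variable), with
#'   attributes `arm_coefficients`, `arm_n`, and `methods` recording any
#'   fallbacks.
#' @export
iv_outcome_coefficient <- function(cohort, iv_name, other_covariates = character()) {
  if (!inherits(cohort, "acce_cohort")) abort_input("`cohort` must be an acce_cohort")
  if (!iv_name %in% names(cohort)) {
    abort_input(paste0("introduced variable not in cohort: ", iv_name))
  }
  outcome <- attr(cohort, "outcome")
  treatment <- attr(cohort, "treatment")
  tr <- cohort_treatment(cohort)
  data <- as.data.frame(cohort)
  terms <- c(iv_name, setdiff(other_covariates, iv_name))
  varies <- vapply(c(0L, 1L), function(arm) {
    length(unique(data[[iv_name]][tr == arm])) > 1L
  }, logical(1))
  if (!all(varies)) {
    warning(paste0("'", iv_name, "' is constant within an arm; ",
                   "falling back to a pooled regression with treatment indicator"),
            call. = FALSE)
    res <- log_risk_coefficient(data, outcome, c(terms, treatment), iv_name)
    return(structure(res$coef, arm_coefficients = NULL,
                     arm_n = c(comparison = sum(tr == 0L), treated = sum(tr == 1L)),
                     methods = res$method))
  }
  arms <- lapply(c(0L, 1L), function(arm) {
    sub <- data[tr == arm, , drop = FALSE]
    # drop adjusters that are constant within this arm
    keep <- terms[vapply(terms, function(tm) length(unique(sub[[tm]])) > 1L, logical(1))]
    log_risk_coefficient(sub, outcome, keep, iv_name)
  })
  n_arm <- c(sum(tr == 0L), sum(tr == 1L))
  coefs <- vapply(arms, `[[`, numeric(1), "coef")
  pooled <- sum(coefs * n_arm) / sum(n_arm)
  structure(pooled,
            arm_coefficients = c(comparison = coefs[1], treated = coefs[2]),
            arm_n = c(comparison = n_arm[1], treated = n_arm[2]),
            methods = vapply(arms, `[[`, character(1), "method"))
}

#' Arm prevalences of a binary Introduced Variable
#'
#' With `fit = NULL`, returns the raw per-arm prevalences. With a
#' propensity fit, returns stratum-size-weighted per-arm prevalences within
#' the propensity-score quantile strata — the balance that model actually
#' achieves, which is what enters the Bross terms.
#'
#' @param cohort An `acce_cohort`.
#' @param iv_name A binary covariate.
#' @param fit An `acce_ps_fit` or `NULL`.
#' @param n_strata Number of quantile strata when `fit` is supplied.
#' @return A list with `prev_treated` and `prev_comparison`.
#' @export
iv_balance <- function(cohort, iv_name, fit = NULL, n_strata = 10L) {
  if (!inherits(cohort, "acce_cohort")) abort_input("`cohort` must be an acce_cohort")
  v <- cohort[[iv_name]]
  if (is.null(v)) abort_input(paste0("introduced variable not in cohort: ", iv_name))
  if (!all(v %in% c(0, 1))) {
    abort_input(paste0(
      "'", iv_name, "' is not binary 0/1; dichotomize it before using it ",
      "in the Bross confounding terms"
    ))
  }
  tr <- cohort_treatment(cohort)
  if (is.null(fit)) {
    return(list(prev_treated = mean(v[tr == 1L]),
                prev_comparison = mean(v[tr == 0L])))
  }
  if (!inherits(fit, "acce_ps_fit")) abort_input("`fit` must be an acce_ps_fit")
  strata <- ps_strata(fit$scores, n_strata)
  prev_arm <- function(arm) {
    in_arm <- tr == arm
    # stratum weights: total stratum size, restricted to strata containing
    # subjects of this arm
    cnt <- rowsum(as.numeric(in_arm), strata)[, 1]
    tot <- rowsum(rep(1, length(tr)), strata)[, 1]
    s <- rowsum(as.numeric(in_arm & v == 1), strata)[, 1]
    ok <- cnt > 0
    sum(tot[ok] * (s[ok] / cnt[ok])) / sum(tot[ok])
  }
  list(prev_treated = prev_arm(1L), prev_comparison = prev_arm(0L))
}

# stratum-size-weighted standardized mean difference of `marker` between
# arms, strata built from the given fit
weighted_smd <- function(cohort, marker, fit, n_strata) {
  tr <- cohort_treatment(cohort)
  v <- cohort[[marker]]
  strata <- ps_strata(fit$scores, n_strata)
  n1 <- rowsum(as.numeric(tr == 1L), strata)[, 1]
  n0 <- rowsum(as.numeric(tr == 0L), strata)[, 1]
  s1 <- rowsum(v * (tr == 1L), strata)[, 1]
  s0 <- rowsum(v * (tr == 0L), strata)[, 1]
  tot <- n1 + n0
  ok <- n1 > 0 & n0 > 0
  diff <- sum(tot[ok] * (s1[ok] / n1[ok] - s0[ok] / n0[ok])) / sum(tot[ok])
  diff / stats::sd(v)
}

#' Empirical amplification from a withheld internal marker
#'
#' Estimates the proportional confounding amplification between the nested
#' models empirically, as the ratio of a withheld covariate's
#' stratum-weighted standardized mean difference between arms under
#' Model 2 to that under Model 1. The marker is deliberately excluded from
#' both propensity models, so the growth of its imbalance indexes the
#' amplification experienced by unmeasured confounders. This strategy may
#' consistently underestimate amplification slightly; a warning to that
#' effect always accompanies the result.
#'
#' @param cohort An `acce_cohort`.
#' @param spec A [nested_model_spec()] with `withheld_marker` set.
#' @return The amplification ratio (usable in place of the R^2-derived
#'   between-model ratio), with attributes `smd_m1` and `smd_m2`.
#' @export
internal_marker_amplification <- function(cohort, spec) {
  if (!inherits(spec, "nested_model_spec")) {
    abort_input("`spec` must be a nested_model_spec")
  }
  marker <- spec$withheld_marker
  if (is.null(marker)) abort_input("`spec$withheld_marker` is not set")
  if (!marker %in% names(cohort)) {
    abort_input(paste0("withheld marker not in cohort: ", marker))
  }
  fit1 <- fit_linear_ps(cohort, spec$model1_covariates)
  fit2 <- fit_linear_ps(cohort, c(spec$model1_covariates, spec$introduced_variables))
  d1 <- weighted_smd(cohort, marker, fit1, spec$n_strata)
  d2 <- weighted_smd(cohort, marker, fit2, spec$n_strata)
  if (abs(d1) < 1e-10) {
    abort_domain("internal marker is balanced under Model 1: amplification ratio undefined")
  }
  warning(paste0(
    "internal-marker amplification may consistently yield a slight ",
    "underestimate of the amount of confounding amplification"
  ), call. = FALSE)
  structure(d2 / d1, smd_m1 = d1, smd_m2 = d2)
}
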