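#' Confounding amplification multiplier of a single propensity model
#'
#' Residual confounding after conditioning on a linear-probability
#' propensity score is amplified, relative to no conditioning at all, in
#' proportion to the unexplained variance in exposure: the multiplier is
#' `1 / (1 - r2)`, where `r2` is the coefficient of determination of the
#' propensity model for treatment exposure. A model with `r2 = 0.5` carries
#' 2-fold amplification; a model that predicts nothing (`r2 = 0`) carries
#' none.
#'
#' @param r2 Coefficient of determination of the propensity model, in
#'   `[0, 1)`.
#' @return The amplification multiplier, a number `>= 1`.
#' @seealso [amplification_increment()] for the between-model quantity the
#'   back-extrapolation actually divides by.
#' @export
#' @examples
#' model_amplification(0.5)  # 2
#' model_amplification(0.25) # 1.333...
model_amplification <- function(r2) {
  if (!is.numeric(r2) || anyNA(r2)) {
    abort_domain("`r2` must be numeric and non-missing")
  }
  if (any(r2 < 0 | r2 >= 1)) {
    abort_domain("`r2` must lie in [0, 1): amplification is undefined at r2 >= 1")
  }
  1 / (1 - r2)
}

#' Proportional confounding amplification between two nested models
#'
#' The back-extrapolation divides the adjusted change in the treatment
#' effect estimate by the amplification occurring *between* Model 1 and
#' Model 2, expressed as an increment above no change:
#' `(1/(1 - r2_m2)) / (1/(1 - r2_m1)) - 1`, algebraically
#' `(r2_m2 - r2_m1) / (1 - r2_m2)`. It is zero when the models predict
#' exposure equally well and negative when Model 2 predicts less well than
#' Model 1 (in which case quantitative extrapolation is invalid).
#'
#' @param r2_m1,r2_m2 Coefficients of determination of the Model 1 and
#'   Model 2 propensity fits, each in `[0, 1)`.
#' @param require_positive If `TRUE`, raise an extrapolation-invalid error
#'   when the increment is `<= 0` (the pipeline does this before dividing by
#'   it). Default `FALSE` so the increment itself can be inspected.
#' @return The amplification increment (a fraction; 0.5 means 50% more
#'   confounding in Model 2 than Model 1).
#' @export
#' @examples
#' amplification_increment(0.25, 0.5) # 0.5
amplification_increment <- function(r2_m1, r2_m2, require_positive = FALSE) {
  stopifnot_number(r2_m1, "r2_m1")
  stopifnot_number(r2_m2, "r2_m2")
  inc <- model_amplification(r2_m2) / model_amplification(r2_m1) - 1
  if (require_positive && inc <= 0) {
    abort_extrapolation(sprintf(
      paste0(
        "amplification increment is %.6g (r2_m1 = %.4g, r2_m2 = %.4g): ",
        "back-extrapolation requires Model 2 to predict exposure strictly ",
        "better than Model 1"
      ),
      inc, r2_m1, r2_m2
    ))
  }
  inc
}

#' Bross-term inputs for a binary confounder
#'
#' Bundles the three quantities the Bross bias formula needs for a binary
#' covariate: its prevalence in each treatment arm and its risk ratio with
#' the outcome (conditional on the other propensity-score covariates).
#'
#' @param prev_treated,prev_comparison Prevalence of the covariate among
#'   treated and comparison subjects, each in `[0, 1]`.
#' @param rr_outcome Covariate-outcome risk ratio, `> 0`.
#' @return An object of class `bross_term`.
#' @export
bross_term <- function(prev_treated, prev_comparison, rr_outcome) {
  stopifnot_number(prev_treated, "prev_treated")
  stopifnot_number(prev_comparison, "prev_comparison")
  stopifnot_number(rr_outcome, "rr_outcome")
  if (prev_treated < 0 || prev_treated > 1 || prev_comparison < 0 || prev_comparison > 1) {
    abort_domain("prevalences must lie in [0, 1]")
  }
  if (rr_outcome <= 0) {
    abort_domain("`rr_outcome` must be a positive risk ratio")
  }
  structure(
    list(
      prev_treated = prev_treated,
      prev_comparison = prev_comparison,
      rr_outcome = rr_outcome
    ),
    class = "bross_term"
  )
}

#' @export
print.bross_term <- function(x, ...) {
  cat(sprintf(
    "Bross term: prevalence %.1f%% (treated) vs %.1f%% (comparison), outcome RR %.4g\n",
    100 * x$prev_treated, 100 * x$prev_comparison, x$rr_outcome
  ))
  cat(sprintf("  log confounding: %.6f\n", bross_log_confounding(x)))
  invisible(x)
}

#' Confounding attributable to a binary covariate (Bross bias formula)
#'
#' For a binary covariate with outcome risk ratio `RR` and arm prevalences
#' `p_t` (treated) and `p_c` (comparison), the multiplicative bias it
#' contributes to a risk-ratio treatment effect estimate is
#' `B = (1 + p_t (RR - 1)) / (1 + p_c (RR - 1))`; the value returned is
#' `log(B)`, the confounding on the log-risk-ratio (beta) scale. It is zero
#' when the arms are balanced or the covariate has no outcome association,
#' and changes sign when the prevalences are swapped.
#'
#' @param term A [bross_term()], or the treated-arm prevalence if the
#'   remaining two arguments are supplied.
#' @param prev_comparison,rr_outcome Comparison-arm prevalence and
#'   covariate-outcome risk ratio, used when `term` is given as a bare
#'   prevalence.
#' @return Confounding on the log-risk-ratio scale.
#' @export
#' @examples
#' bross_log_confounding(0.80, 0.20, 1.05) # 0.0293 to 4 d.p.
bross_log_confounding <- function(term, prev_comparison = NULL, rr_outcome = NULL) {
  if (!inherits(term, "bross_term")) {
    term <- bross_term(term, prev_comparison, rr_outcome)
  }
  num <- 1 + term$prev_treated * (term$rr_outcome - 1)
  den <- 1 + term$prev_comparison * (term$rr_outcome - 1)
  if (num <= 0 || den <= 0) {
    abort_domain("Bross bias factor undefined: a risk term is non-positive")
  }
  log(num) - log(den)
}

#' Change in Introduced-Variable confounding between the nested models
#'
#' When the Introduced Variable enters the Model 2 propensity score it
#' becomes more balanced, so its contribution to confounding changes
#' (usually shrinks). This function returns the Bross-estimated change,
#' Model 2 term minus Model 1 term; it is negative when balance improves
#' for a treated-excess covariate with outcome RR above 1.
#'
#' @param balance_m1,balance_m2 [bross_term()] objects describing the
#'   covariate's arm balance under Model 1 and Model 2. Both must carry the
#'   same `rr_outcome`.
#' @return Change in confounding on the log-risk-ratio scale.
#' @export
#' @examples
#' delta_iv_confounding(
#'   bross_term(0.80, 0.20, 1.05),
#'   bross_term(0.52, 0.48, 1.05)
#' ) # -0.0273 to 4 d.p.
delta_iv_confounding <- function(balance_m1, balance_m2) {
  if (!inherits(balance_m1, "bross_term") || !inherits(balance_m2, "bross_term")) {
    abort_input("`balance_m1` and `balance_m2` must be bross_term objects")
  }
  if (!isTRUE(all.equal(balance_m1$rr_outcome, balance_m2$rr_outcome, tolerance = 1e-12))) {
    abort_input("the two balance terms must share the same covariate-outcome risk ratio")
  }
  bross_log_confounding(balance_m2) - bross_log_confounding(balance_m1)
}

#' Between-model change in the treatment effect estimate, adjusted for the
#' Introduced Variable
#'
#' Subtracts from the observed change in the treatment effect estimate
#' (Model 2 beta minus Model 1 beta) the part attributable to the improved
#' balance of the Introduced Variable(s), leaving the change due to
#' confounding amplification alone.
#'
#' @param tee_m1,tee_m2 Treatment effect estimates on the log-risk-ratio
#'   scale.
#' @param conf_iv_delta Bross-estimated change in Introduced-Variable
#'   confounding between the models (see [delta_iv_confounding()]).
#' @return The adjusted change on the log-risk-ratio scale.
#' @export
adjusted_delta_tee <- function(tee_m1, tee_m2, conf_iv_delta) {
  stopifnot_number(tee_m1, "tee_m1")
  stopifnot_number(tee_m2, "tee_m2")
  stopifnot_number(conf_iv_delta, "conf_iv_delta")
  (tee_m2 - tee_m1) - conf_iv_delta
}

#' Back-extrapolated amplifiable-fraction confounding
#'
#' Divides the adjusted between-model change in the treatment effect
#' estimate by the amplification increment, extrapolating back to the
#' Model 1 residual confounding contributed by confounders absent from both
#' models (the "amplifiable fraction", symbolically `x`).
#'
#' @param adj_delta Adjusted between-model change on the log-risk-ratio
#'   scale (see [adjusted_delta_tee()]).
#' @param r2_m1,r2_m2 Propensity-model coefficients of determination, used
#'   to derive the increment when `increment` is not supplied.
#' @param increment Optionally the amplification increment itself (e.g.
#'   from an internal-marker estimate); must be `> 0`.
#' @return Amplifiable-fraction confounding on the log-risk-ratio scale.
#' @export
#' @examples
#' amplifiable_confounding(0.0534, 0.25, 0.5) # 0.1068
amplifiable_confounding <- function(adj_delta, r2_m1 = NULL, r2_m2 = NULL,
                                    increment = NULL) {
  stopifnot_number(adj_delta, "adj_delta")
  if (is.null(increment)) {
    if (is.null(r2_m1) || is.null(r2_m2)) {
      abort_input("supply either both `r2_m1` and `r2_m2` or `increment`")
    }
    increment <- amplification_increment(r2_m1, r2_m2, require_positive = TRUE)
  } else {
    stopifnot_number(increment, "increment")
    if (increment <= 0) {
      abort_extrapolation("amplification increment must be positive to extrapolate")
    }
  }
  adj_delta / increment
}

#' Assemble the summary-equation inputs
#'
#' Collects every term of the summary equation: the two treatment effect
#' estimates (log-risk-ratio scale), the two propensity-model R^2 values,
#' the Bross-estimated change in Introduced-Variable confounding between
#' the models, and the Introduced Variable's Model 1 confounding relative
#' to perfect balance.
#'
#' @param tee_m1,tee_m2 Treatment effect estimates, log-risk-ratio scale.
#' @param r2_m1,r2_m2 Propensity-model coefficients of determination, each
#'   in `[0, 1)`.
#' @param conf_iv_delta Change in Introduced-Variable confounding between
#'   Model 2 and Model 1 (log-RR scale). Default 0 (true instrument).
#' @param conf_iv_m1 Introduced-Variable confounding present in Model 1
#'   (log-RR scale). Default 0.
#' @return An object of class `acce_inputs`.
#' @export
acce_inputs <- function(tee_m1, tee_m2, r2_m1, r2_m2,
                        conf_iv_delta = 0, conf_iv_m1 = 0) {
  stopifnot_number(tee_m1, "tee_m1")
  stopifnot_number(tee_m2, "tee_m2")
  stopifnot_number(r2_m1, "r2_m1")
  stopifnot_number(r2_m2, "r2_m2")
  stopifnot_number(conf_iv_delta, "conf_iv_delta")
  stopifnot_number(conf_iv_m1, "conf_iv_m1")
  if (r2_m1 < 0 || r2_m1 >= 1 || r2_m2 < 0 || r2_m2 >= 1) {
    abort_domain("R^2 values must lie in [0, 1)")
  }
  structure(
    list(
      tee_m1 = tee_m1, tee_m2 = tee_m2,
      r2_m1 = r2_m1, r2_m2 = r2_m2,
      conf_iv_delta = conf_iv_delta, conf_iv_m1 = conf_iv_m1
    ),
    class = "acce_inputs"
  )
}

#' @export
print.acce_inputs <- function(x, ...) {
  cat("Summary-equation inputs (log-RR scale)\n")
  cat(sprintf("  TEE_M1 = %.6f (RR %.4f), TEE_M2 = %.6f (RR %.4f)\n",
              x$tee_m1, exp(x$tee_m1), x$tee_m2, exp(x$tee_m2)))
  cat(sprintf("  R2_M1 = %.4f, R2_M2 = %.4f\n", x$r2_m1, x$r2_m2))
  cat(sprintf("  Conf_IntV_delta = %.6f, Conf_IntV_M1 = %.6f\n",
              x$conf_iv_delta, x$conf_iv_m1))
  invisible(x)
}

# validity band within which the 1/(1 - R^2) amplification law has
# simulation support; estimates outside it are flagged, not refused
r2_validated_range <- c(0.04, 0.56)

#' Unconfounded treatment effect by the summary equation
#'
#' Runs the full back-extrapolation: the adjusted between-model change in
#' the treatment effect estimate is divided by the amplification increment
#' to give the amplifiable-fraction confounding `x`; adding the Introduced
#' Variable's own Model 1 confounding gives total Model 1 residual
#' confounding; subtracting that total from the Model 1 treatment effect
#' estimate gives the unconfounded estimate `k`.
#'
#' Estimates are flagged (not refused) when either propensity R^2 falls
#' outside `[0.04, 0.56]`, the range over which the linear relationship
#' between `1 - R^2` and amplification has simulation support.
#'
#' @param inputs An [acce_inputs()] object.
#' @param thresholds Qualitative classification thresholds, see
#'   [probe_thresholds()].
#' @return An object of class `acce_result` with components
#'   `amplifiable_confounding` (`x`), `total_residual_confounding`,
#'   `unconfounded_tee` (`k`), `adj_delta_tee`, `amplification_increment`,
#'   the echoed inputs, a `qualitative` probe classification and a
#'   character vector of `warnings`.
#' @export
#' @examples
#' res <- unconfounded_tee(acce_inputs(
#'   tee_m1 = 0.235072, tee_m2 = 0.2612, r2_m1 = 0.25, r2_m2 = 0.5
#' ))
#' res$unconfounded_tee # 0.1828 (RR about 1.20)
unconfounded_tee <- function(inputs, thresholds = probe_thresholds()) {
  if (!inherits(inputs, "acce_inputs")) {
    abort_input("`inputs` must be an acce_inputs object")
  }
  warnings <- character()
  inc <- amplification_increment(inputs$r2_m1, inputs$r2_m2, require_positive = TRUE)
  adj <- adjusted_delta_tee(inputs$tee_m1, inputs$tee_m2, inputs$conf_iv_delta)
  x <- adj / inc
  total <- x + inputs$conf_iv_m1
  k <- inputs$tee_m1 - total
  out_of_band <- c(inputs$r2_m1, inputs$r2_m2) < r2_validated_range[1] |
    c(inputs$r2_m1, inputs$r2_m2) > r2_validated_range[2]
  if (any(out_of_band)) {
    warnings <- c(warnings, sprintf(
      "propensity R^2 (%s) outside [%.2f, %.2f], the range with simulation support for 1/(1-R^2) amplification",
      paste(sprintf("%.3f", c(inputs$r2_m1, inputs$r2_m2)[out_of_band]), collapse = ", "),
      r2_validated_range[1], r2_validated_range[2]
    ))
  }
  probe <- qualitative_probe(inputs$tee_m1, inputs$tee_m2, thresholds = thresholds)
  structure(
    list(
      inputs = inputs,
      amplification_m1 = model_amplification(inputs$r2_m1),
      amplification_m2 = model_amplification(inputs$r2_m2),
      amplification_increment = inc,
      adj_delta_tee = adj,
      amplifiable_confounding = x,
      total_residual_confounding = total,
      unconfounded_tee = k,
      qualitative = probe,
      warnings = warnings
    ),
    class = "acce_result"
  )
}

#' @export
print.acce_result <- function(x, digits = 4, ...) {
  inp <- x$inputs
  cat("Amplified-confounding estimate of residual confounding\n")
  cat(sprintf("  TEE Model 1: beta %.*f (RR %.*f);  Model 2: beta %.*f (RR %.*f)\n",
              digits, inp$tee_m1, digits, exp(inp$tee_m1),
              digits, inp$tee_m2, digits, exp(inp$tee_m2)))
  cat(sprintf("  Propensity R^2: %.*f -> %.*f (amplification increment %.*f)\n",
              digits, inp$r2_m1, digits, inp$r2_m2, digits, x$amplification_increment))
  cat(sprintf("  Adjusted delta TEE:            %.*f\n", digits, x$adj_delta_tee))
  cat(sprintf("  Amplifiable confounding (x):   %.*f\n", digits, x$amplifiable_confounding))
  cat(sprintf("  Introduced-Variable conf (M1): %.*f\n", digits, inp$conf_iv_m1))
  cat(sprintf("  Total residual confounding:    %.*f\n", digits, x$total_residual_confounding))
  cat(sprintf("  Unconfounded TEE (k):          %.*f (RR %.*f)\n",
              digits, x$unconfounded_tee, digits, exp(x$unconfounded_tee)))
  cat(sprintf("  Qualitative probe: %s, %s (delta beta %.*f)\n",
              x$qualitative$magnitude, x$qualitative$direction,
              digits, x$qualitative$delta_beta))
  if (length(x$warnings)) {
    cat("  Warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
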