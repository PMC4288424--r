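#' Thresholds for the qualitative probe classification
#'
#' Cutoffs on the absolute between-model change in beta (log-risk-ratio)
#' used by [qualitative_probe()]. A change below `negligible` is treated as
#' no change; below `small` as a small change; at or above `small` as
#' sizeable. Defaults (0.01, 0.05) bracket the real-data illustrations in
#' which a mortality analysis shifting RR 0.84 to 0.82 (|delta beta| about
#' 0.024) reads as small and a hip-fracture analysis shifting 0.76 to 0.69
#' (about 0.097) reads as sizeable.
#'
#' @param negligible,small Positive cutoffs with `negligible < small`.
#' @return A classed list of thresholds.
#' @export
probe_thresholds <- function(negligible = 0.01, small = 0.05) {
  stopifnot_number(negligible, "negligible")
  stopifnot_number(small, "small")
  if (negligible <= 0 || small <= negligible) {
    abort_input("thresholds must satisfy 0 < negligible < small")
  }
  structure(list(negligible = negligible, small = small),
            class = "acce_probe_thresholds")
}

#' Qualitative probe: direction and size of the between-model shift
#'
#' Even when the quantitative back-extrapolation is unavailable (e.g. no
#' usable R^2), the direction and size of the change in the treatment
#' effect estimate upon adding the Introduced Variable is itself
#' informative: amplification pushes the estimate further in the direction
#' residual confounding is already biasing it. A shift away from the null
#' therefore implies residual confounding away from the null, with its size
#' indexing the amount.
#'
#' @param tee_m1,tee_m2 Treatment effect estimates. Interpreted on the
#'   log-risk-ratio scale unless `scale = "rr"`, in which case they are
#'   risk (or hazard) ratios and are logged internally.
#' @param thresholds A [probe_thresholds()] object.
#' @param scale `"beta"` (default) or `"rr"`.
#' @return An object of class `acce_probe`: `direction` (one of
#'   `"toward_null"`, `"away_from_null"`, `"no_change"`), `magnitude`
#'   (`"negligible"`, `"small"`, `"sizeable"`), `delta_beta`, and any
#'   `warnings`.
#' @export
#' @examples
#' qualitative_probe(0.84, 0.82, scale = "rr") # away from null, small
qualitative_probe <- function(tee_m1, tee_m2, thresholds = probe_thresholds(),
                              scale = c("beta", "rr")) {
  scale <- match.arg(scale)
  stopifnot_number(tee_m1, "tee_m1")
  stopifnot_number(tee_m2, "tee_m2")
  if (!inherits(thresholds, "acce_probe_thresholds")) {
    abort_input("`thresholds` must come from probe_thresholds()")
  }
  if (scale == "rr") {
    if (tee_m1 <= 0 || tee_m2 <= 0) abort_domain("risk ratios must be positive")
    tee_m1 <- log(tee_m1)
    tee_m2 <- log(tee_m2)
  }
  delta <- tee_m2 - tee_m1
  warnings <- character()
  magnitude <- if (abs(delta) < thresholds$negligible) {
    "negligible"
  } else if (abs(delta) < thresholds$small) {
    "small"
  } else {
    "sizeable"
  }
  if (abs(delta) < thresholds$negligible) {
    direction <- "no_change"
  } else if (tee_m1 == 0) {
    direction <- "away_from_null"
    warnings <- c(warnings,
                  "Model 1 estimate is exactly null; any shift is away from it")
  } else if (sign(delta) == sign(tee_m1)) {
    direction <- "away_from_null"
  } else {
    direction <- "toward_null"
  }
  structure(
    list(direction = direction, magnitude = magnitude,
         delta_beta = delta, thresholds = thresholds, warnings = warnings),
    class = "acce_probe"
  )
}

#' @export
print.acce_probe <- function(x, ...) {
  cat(sprintf("Qualitative probe: %s change, %s (delta beta = %.4f)\n",
              x$magnitude, gsub("_", " ", x$direction), x$delta_beta))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
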