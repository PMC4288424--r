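# Classed conditions so callers (and the bootstrap) can distinguish
# recoverable extrapolation failures from genuine input errors.

acce_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "acce_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# domain of an arithmetic operation violated (e.g. R^2 outside [0,1))
abort_domain <- function(message) acce_abort(message, "acce_domain_error")

# back-extrapolation undefined: amplification increment <= 0, R^2 = 1, ...
abort_extrapolation <- function(message) acce_abort(message, "acce_extrapolation_error")

# malformed user input (mismatched terms, bad coding, unknown config keys)
abort_input <- function(message) acce_abort(message, "acce_input_error")

# estimation impossible on the data at hand (all strata degenerate, no events)
abort_estimation <- function(message) acce_abort(message, "acce_estimation_error")

# bootstrap/inference level failures
abort_inference <- function(message) acce_abort(message, "acce_inference_error")

stopifnot_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_input(sprintf("`%s` must be a single non-missing number", name))
  }
  if (finite && !is.finite(x)) {
    abort_input(sprintf("`%s` must be finite", name))
  }
  invisible(x)
}
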