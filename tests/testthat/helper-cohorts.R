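# Shared in-code fixtures. All cohorts are built programmatically so tests
# carry no data files.

# tiny deterministic cohort: treatment tracks x1, outcome tracks treatment
toy_cohort <- function() {
  as_cohort(data.frame(
    treatment = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L),
    outcome   = c(1L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 1L, 0L),
    x1        = c(2.0, 1.5, 1.8, 1.1, 0.4, 0.2, 0.9, 0.5, 1.3, 0.7),
    iv        = c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L)
  ), iv_columns = "iv")
}

# cohort with prescribed per-arm outcome risks and no covariate structure;
# counts are exact so crude risk ratios are known in closed form
risk_cohort <- function(n_treated, events_treated, n_comparison, events_comparison) {
  as_cohort(data.frame(
    treatment = rep(c(1L, 0L), c(n_treated, n_comparison)),
    outcome = c(rep(c(1L, 0L), c(events_treated, n_treated - events_treated)),
                rep(c(1L, 0L), c(events_comparison, n_comparison - events_comparison))),
    x1 = seq_len(n_treated + n_comparison) * 0.001
  ))
}

# default analysis specification for simulated cohorts
sim_spec <- function(...) nested_model_spec("conf_measured", "iv", ...)

expect_acce_error <- function(expr, class) {
  expect_error(expr, class = class)
}
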