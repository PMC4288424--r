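# Orchestration: config-driven runs and the JSON report writer.

run_modes <- c("cohort", "calculator", "simulate", "example")

config_keys <- list(
  common = c("mode", "out", "seed", "probe_negligible", "probe_small"),
  calculator = c("tee_m1_beta", "tee_m1_rr", "tee_m2_beta", "tee_m2_rr",
                 "r2_m1", "r2_m2", "iv_rr_outcome",
                 "iv_prev_treated_m1", "iv_prev_comparison_m1",
                 "iv_prev_treated_m2", "iv_prev_comparison_m2",
                 "conf_iv_delta", "conf_iv_m1"),
  example = "example_id",
  cohort = c("cohort_csv", "treatment_col", "outcome_col",
             "model1_covariates", "introduced_variables", "n_strata",
             "withheld_marker", "m1_balance", "bootstrap", "ci_level",
             "stratified_by_arm"),
  simulate = c("n", "genuine_effect_k", "measured_confounder_exposure",
               "measured_confounder_outcome", "iv_exposure_weight",
               "iv_outcome_logrr", "iv_prevalence",
               "unmeasured_exposure", "unmeasured_outcome",
               "iv_unmeasured_correlation", "baseline_risk",
               "treatment_base", "export_csv",
               "model1_covariates", "introduced_variables", "n_strata",
               "withheld_marker", "m1_balance", "bootstrap", "ci_level",
               "stratified_by_arm")
)

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` flat key/value config.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_input(paste0("config file not found: ", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort_input("config must be a .yaml, .yml or .json file")
  }
}

validate_config <- function(config) {
  if (!is.list(config)) abort_input("config must be a named list")
  mode <- config[["mode"]]
  if (is.null(mode) || !mode %in% run_modes) {
    abort_input(paste0("config `mode` must be one of: ",
                       paste(run_modes, collapse = ", ")))
  }
  allowed <- c(config_keys$common, config_keys[[mode]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    abort_input(paste0("unknown config key(s) for mode '", mode, "': ",
                       paste(unknown, collapse = ", ")))
  }
  config
}

config_thresholds <- function(config) {
  probe_thresholds(
    negligible = config[["probe_negligible"]] %||% 0.01,
    small = config[["probe_small"]] %||% 0.05
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

beta_from_config <- function(config, which) {
  beta_key <- paste0(which, "_beta")
  rr_key <- paste0(which, "_rr")
  if (!is.null(config[[beta_key]])) return(config[[beta_key]])
  if (!is.null(config[[rr_key]])) {
    rr <- config[[rr_key]]
    stopifnot_number(rr, rr_key)
    if (rr <= 0) abort_domain(paste0("`", rr_key, "` must be a positive risk ratio"))
    return(log(rr))
  }
  abort_input(paste0("calculator mode needs `", beta_key, "` or `", rr_key, "`"))
}

calculator_inputs <- function(config) {
  tee_m1 <- beta_from_config(config, "tee_m1")
  tee_m2 <- beta_from_config(config, "tee_m2")
  if (is.null(config[["r2_m1"]]) || is.null(config[["r2_m2"]])) {
    abort_input("calculator mode needs `r2_m1` and `r2_m2`")
  }
  conf_delta <- config[["conf_iv_delta"]]
  conf_m1 <- config[["conf_iv_m1"]]
  if (!is.null(config[["iv_rr_outcome"]])) {
    needed <- c("iv_prev_treated_m1", "iv_prev_comparison_m1",
                "iv_prev_treated_m2", "iv_prev_comparison_m2")
    if (!all(needed %in% names(config))) {
      abort_input(paste0("`iv_rr_outcome` requires ",
                         paste(needed, collapse = ", ")))
    }
    term1 <- bross_term(config[["iv_prev_treated_m1"]], config[["iv_prev_comparison_m1"]],
                        config[["iv_rr_outcome"]])
    term2 <- bross_term(config[["iv_prev_treated_m2"]], config[["iv_prev_comparison_m2"]],
                        config[["iv_rr_outcome"]])
    conf_delta <- delta_iv_confounding(term1, term2)
    conf_m1 <- bross_log_confounding(term1)
  }
  acce_inputs(tee_m1, tee_m2, config[["r2_m1"]], config[["r2_m2"]],
              conf_iv_delta = conf_delta %||% 0,
              conf_iv_m1 = conf_m1 %||% 0)
}

spec_from_config <- function(config) {
  if (is.null(config[["model1_covariates"]]) || is.null(config[["introduced_variables"]])) {
    abort_input("cohort/simulate mode needs `model1_covariates` and `introduced_variables`")
  }
  nested_model_spec(
    model1_covariates = as.character(config[["model1_covariates"]]),
    introduced_variables = as.character(config[["introduced_variables"]]),
    n_strata = config[["n_strata"]] %||% 10L,
    withheld_marker = config[["withheld_marker"]],
    m1_balance = config[["m1_balance"]] %||% "stratified"
  )
}

scenario_from_config <- function(config, seed) {
  defaults <- sim_scenario()
  sim_scenario(
    n = config[["n"]] %||% defaults$n,
    genuine_effect_k = config[["genuine_effect_k"]] %||% defaults$genuine_effect_k,
    measured_confounder_coeffs = c(
      exposure = config[["measured_confounder_exposure"]] %||%
        defaults$measured_confounder_coeffs[["exposure"]],
      outcome = config[["measured_confounder_outcome"]] %||%
        defaults$measured_confounder_coeffs[["outcome"]]
    ),
    iv_exposure_weight = config[["iv_exposure_weight"]] %||% defaults$iv_exposure_weight,
    iv_outcome_logrr = config[["iv_outcome_logrr"]] %||% defaults$iv_outcome_logrr,
    iv_prevalence = config[["iv_prevalence"]] %||% defaults$iv_prevalence,
    unmeasured_confounder_coeffs = if (!is.null(config[["unmeasured_exposure"]])) {
      mapply(function(e, o) c(exposure = e, outcome = o),
             config[["unmeasured_exposure"]],
             config[["unmeasured_outcome"]] %||% rep(0, length(config[["unmeasured_exposure"]])),
             SIMPLIFY = FALSE)
    } else {
      defaults$unmeasured_confounder_coeffs
    },
    iv_unmeasured_correlation = config[["iv_unmeasured_correlation"]] %||% 0,
    baseline_risk = config[["baseline_risk"]] %||% defaults$baseline_risk,
    treatment_base = config[["treatment_base"]] %||% defaults$treatment_base,
    seed = seed
  )
}

result_report <- function(result, config, bootstrap = NULL) {
  inp <- result$inputs
  intermediates <- list(
    TEE_M1 = inp$tee_m1,
    TEE_M2 = inp$tee_m2,
    R2_M1 = inp$r2_m1,
    R2_M2 = inp$r2_m2,
    Conf_IntV_delta = inp$conf_iv_delta,
    Conf_IntV_M1 = inp$conf_iv_m1,
    Adj_delta_TEE = result$adj_delta_tee,
    amplification_M1 = result$amplification_m1,
    amplification_M2 = result$amplification_m2,
    amplification_increment = result$amplification_increment,
    x = result$amplifiable_confounding,
    total_residual_confounding = result$total_residual_confounding,
    k = result$unconfounded_tee,
    Unconfounded_TEE = result$unconfounded_tee,
    Unconfounded_RR = exp(result$unconfounded_tee)
  )
  report <- list(
    tool = "acce",
    version = as.character(utils::packageVersion("acce")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    mode = config[["mode"]],
    seed = config[["seed"]] %||% NA,
    inputs = config,
    intermediates = intermediates,
    display_4dp = lapply(intermediates, function(v) round(v, 4)),
    qualitative = list(
      direction = result$qualitative$direction,
      magnitude = result$qualitative$magnitude,
      delta_beta = result$qualitative$delta_beta
    ),
    warnings = result$warnings
  )
  if (!is.null(bootstrap)) {
    report$bootstrap <- list(
      replicates = bootstrap$replicates,
      level = bootstrap$level,
      point = bootstrap$point,
      ci_low = bootstrap$ci_low,
      ci_high = bootstrap$ci_high,
      failed_replicates = bootstrap$failed_replicates
    )
  }
  report
}

#' Run the method end-to-end from a configuration
#'
#' Executes one of four modes and (optionally) writes a JSON report
#' containing every intermediate quantity of the summary equation at full
#' precision plus a 4-decimal display block:
#' \describe{
#'   \item{`calculator`}{evaluate the summary equation from pre-computed
#'     inputs (`tee_m1_beta`/`tee_m1_rr`, `tee_m2_beta`/`tee_m2_rr`,
#'     `r2_m1`, `r2_m2`, and either direct `conf_iv_*` terms or
#'     `iv_rr_outcome` with the four arm prevalences).}
#'   \item{`example`}{run one of the four built-in worked examples
#'     (`example_id`).}
#'   \item{`cohort`}{read a cohort CSV (`cohort_csv`, `treatment_col`,
#'     `outcome_col`) and run the full pipeline for the given
#'     `model1_covariates` and `introduced_variables`; optional `bootstrap`
#'     replicates and `ci_level`.}
#'   \item{`simulate`}{generate a synthetic cohort from scenario keys,
#'     optionally export it (`export_csv`), then run the pipeline.}
#' }
#'
#' @param config A named list, or a path to a YAML/JSON config file.
#' @param out Optional output path for the JSON report (overrides the
#'   config's `out`).
#' @param quiet Suppress progress messages.
#' @return The report, invisibly, as a named list.
#' @export
run_acce <- function(config, out = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  config <- validate_config(config)
  say <- function(...) if (!quiet) message(...)
  thresholds <- config_thresholds(config)
  seed <- as.integer(config[["seed"]] %||% 1L)
  bootstrap <- NULL

  if (config[["mode"]] == "calculator") {
    say("Evaluating summary equation from supplied inputs")
    result <- unconfounded_tee(calculator_inputs(config), thresholds = thresholds)
  } else if (config[["mode"]] == "example") {
    if (is.null(config[["example_id"]])) abort_input("example mode needs `example_id`")
    say("Evaluating worked example ", config[["example_id"]])
    result <- unconfounded_tee(example_fixture(as.integer(config[["example_id"]])),
                               thresholds = thresholds)
  } else {
    if (config[["mode"]] == "cohort") {
      if (is.null(config[["cohort_csv"]])) abort_input("cohort mode needs `cohort_csv`")
      say("Reading cohort from ", config[["cohort_csv"]])
      cohort <- read_cohort(config[["cohort_csv"]],
                            treatment = config[["treatment_col"]] %||% "treatment",
                            outcome = config[["outcome_col"]] %||% "outcome")
    } else {
      scenario <- scenario_from_config(config, seed)
      say("Step 0: generating synthetic cohort (n = ", scenario$n, ")")
      cohort <- generate_cohort(scenario)
      if (!is.null(config[["export_csv"]])) write_cohort(cohort, config[["export_csv"]])
    }
    spec <- spec_from_config(config)
    say("Step 1: fitting nested propensity models (Model 1: ",
        paste(spec$model1_covariates, collapse = " + "), "; Introduced: ",
        paste(spec$introduced_variables, collapse = " + "), ")")
    say("Step 2: stratified treatment effect estimates and R^2 pair")
    say("Step 3: Introduced Variable outcome coefficients and Bross terms")
    say("Step 4: back-extrapolation via the summary equation")
    result <- acce_cohort(cohort, spec, thresholds = thresholds)
    if (!is.null(config[["bootstrap"]]) && config[["bootstrap"]] > 0) {
      say("Bootstrapping (", config[["bootstrap"]], " replicates)")
      bootstrap <- bootstrap_ci(cohort, spec,
                                B = as.integer(config[["bootstrap"]]),
                                level = config[["ci_level"]] %||% 0.95,
                                seed = seed,
                                stratified_by_arm = isTRUE(config[["stratified_by_arm"]]))
    }
  }

  report <- result_report(result, config, bootstrap = bootstrap)
  out <- out %||% config[["out"]]
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    say("Report written to ", out)
  }
  invisible(report)
}
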