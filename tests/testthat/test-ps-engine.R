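# Propensity fitting, stratified effect estimation, Introduced Variable
# balance/coefficient machinery, and the internal-marker estimator.

test_that("fit_linear_ps matches closed-form OLS R^2 on a hand fixture", {
  # single covariate: R^2 is the squared Pearson correlation
  df <- data.frame(
    treatment = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L),
    outcome   = c(1L, 0L, 0L, 0L, 1L, 1L, 0L, 0L),
    x1        = c(2.3, 0.1, 1.7, 0.6, 2.9, 1.2, 1.4, 0.3)
  )
  coh <- as_cohort(df)
  fit <- fit_linear_ps(coh, "x1")
  expect_equal(fit$r2, cor(df$treatment, df$x1)^2, tolerance = 1e-12)
  # fitted scores agree with closed-form simple-regression coefficients
  b1 <- cov(df$x1, df$treatment) / var(df$x1)
  b0 <- mean(df$treatment) - b1 * mean(df$x1)
  expect_equal(unname(fit$scores), unname(b0 + b1 * df$x1), tolerance = 1e-12)
})

test_that("fit_linear_ps R^2 is tiny under independence and invariant to affine rescaling", {
  set.seed(5)
  n <- 10000
  coh <- as_cohort(data.frame(
    treatment = rbinom(n, 1, 0.5),
    outcome = rbinom(n, 1, 0.1),
    x1 = rnorm(n), x2 = rnorm(n)
  ))
  fit <- fit_linear_ps(coh, c("x1", "x2"))
  expect_lt(fit$r2, 0.01)
  rescaled <- as.data.frame(coh)
  rescaled$x1 <- 100 * rescaled$x1 - 7
  rescaled$x2 <- -0.01 * rescaled$x2 + 3
  fit2 <- fit_linear_ps(as_cohort(rescaled), c("x1", "x2"))
  expect_equal(fit2$r2, fit$r2, tolerance = 1e-10)
})

test_that("singular designs and perfect separation raise classed errors", {
  coh <- toy_cohort()
  dup <- as.data.frame(coh)
  dup$x1_copy <- dup$x1
  expect_error(fit_linear_ps(as_cohort(dup, iv_columns = "iv"), c("x1", "x1_copy")),
               regexp = "x1_copy", class = "acce_input_error")
  sep <- as.data.frame(coh)
  sep$exact <- as.numeric(sep$treatment)
  expect_error(fit_linear_ps(as_cohort(sep), "exact"),
               class = "acce_extrapolation_error")
})

test_that("single-stratum Mantel-Haenszel equals the crude risk ratio", {
  coh <- risk_cohort(100, 10, 100, 5)
  tee <- estimate_tee_stratified(coh, fit = NULL, n_strata = 1)
  expect_equal(tee$beta, log(2.0), tolerance = 1e-12)
  # constant scores: stratified equals crude whatever n_strata
  fit <- structure(list(scores = rep(0.5, nrow(coh)), r2 = 0,
                        coefficients = 0, covariates = "x1", n = nrow(coh)),
                   class = "acce_ps_fit")
  tee10 <- suppressWarnings(estimate_tee_stratified(coh, fit, n_strata = 10))
  expect_equal(tee10$beta, log(2.0), tolerance = 1e-6)
})

test_that("Mantel-Haenszel pooling matches direct 2x2 arithmetic on two strata", {
  # stratum 1: treated 30 (6 events), comparison 10 (1 event)
  # stratum 2: treated 10 (1 event),  comparison 30 (3 events)
  df <- data.frame(
    treatment = c(rep(1L, 30), rep(0L, 10), rep(1L, 10), rep(0L, 30)),
    outcome = c(rep(c(1L, 0L), c(6, 24)), rep(c(1L, 0L), c(1, 9)),
                rep(c(1L, 0L), c(1, 9)), rep(c(1L, 0L), c(3, 27))),
    x1 = c(rep(0, 40), rep(1, 40))
  )
  coh <- as_cohort(df)
  fit <- fit_linear_ps(coh, "x1")
  tee <- estimate_tee_stratified(coh, fit, n_strata = 2)
  # independent oracle: MH RR = sum(a_i n0_i / T_i) / sum(b_i n1_i / T_i)
  mh <- (6 * 10 / 40 + 1 * 30 / 40) / (1 * 30 / 40 + 3 * 10 / 40)
  expect_equal(tee$rr, mh, tolerance = 1e-12)
  expect_equal(tee$n_strata_used, 2L)
})

test_that("degenerate strata are dropped with a warning; all-degenerate errors", {
  # arms overlap only in mid-range x1, so extreme score strata are one-armed
  set.seed(2)
  df <- data.frame(
    treatment = rep(c(1L, 0L), c(30, 30)),
    outcome = rbinom(60, 1, 0.4),
    x1 = c(seq(0.5, 2, length.out = 30), seq(0, 1.5, length.out = 30))
  )
  coh <- as_cohort(df)
  fit <- fit_linear_ps(coh, "x1")
  expect_warning(tee <- estimate_tee_stratified(coh, fit, n_strata = 6),
                 regexp = "dropped")
  expect_lt(tee$n_strata_used, 6L)
  # no events at all -> estimation error
  none <- as.data.frame(risk_cohort(50, 0, 50, 0))
  expect_error(estimate_tee_stratified(as_cohort(none), NULL, 1),
               class = "acce_estimation_error")
})

test_that("adding the Introduced Variable never decreases R^2", {
  for (seed in 1:5) {
    coh <- suppressWarnings(generate_cohort(sim_scenario(n = 4000), seed = seed))
    f1 <- fit_linear_ps(coh, "conf_measured")
    f2 <- fit_linear_ps(coh, c("conf_measured", "iv"))
    expect_gte(f2$r2, f1$r2)
  }
})

test_that("iv_outcome_coefficient is near zero under a null association", {
  # outcome independent of the IV within arms, no unmeasured confounding;
  # averaged over replicates to beat the per-cohort sampling noise
  sc <- sim_scenario(n = 100000, iv_outcome_logrr = 0,
                     unmeasured_confounder_coeffs = list(c(exposure = 0, outcome = 0)),
                     seed = 19)
  coefs <- sapply(1:4, function(i) {
    coh <- suppressWarnings(generate_cohort(sc, seed = sc$seed + i))
    as.numeric(iv_outcome_coefficient(coh, "iv", "conf_measured"))
  })
  expect_lt(abs(mean(coefs)), 0.02)
})

test_that("iv_outcome_coefficient recovers a known coefficient without collider pressure", {
  # true IV-outcome log-RR 0.04879 (RR 1.05); no unmeasured confounders, so
  # the within-arm regressions are unconfounded and uncontaminated
  sc <- sim_scenario(n = 100000, iv_outcome_logrr = 0.04879,
                     unmeasured_confounder_coeffs = list(c(exposure = 0, outcome = 0)),
                     seed = 23)
  coh <- suppressWarnings(generate_cohort(sc))
  co <- iv_outcome_coefficient(coh, "iv", "conf_measured")
  expect_lt(abs(as.numeric(co) - 0.04879), 0.025)
})

test_that("arm pooling is the arm-size-weighted mean, and equal arms give the simple mean", {
  coh <- toy_cohort()
  co <- iv_outcome_coefficient(coh, "iv", character())
  arms <- attr(co, "arm_coefficients")
  ns <- attr(co, "arm_n")
  expect_equal(as.numeric(co),
               sum(arms * ns) / sum(ns), tolerance = 1e-12)
  expect_equal(unname(ns), c(5, 5)) # equal arms here
  expect_equal(as.numeric(co), mean(arms), tolerance = 1e-12)
})

test_that("iv constant within an arm falls back to a pooled regression with warning", {
  df <- as.data.frame(toy_cohort())
  df$iv[df$treatment == 1] <- 1L
  coh <- as_cohort(df, iv_columns = "iv")
  expect_warning(co <- iv_outcome_coefficient(coh, "iv", character()),
                 regexp = "constant within an arm")
  expect_true(is.finite(as.numeric(co)))
})

test_that("iv_balance counts raw prevalences exactly and rejects non-binary variables", {
  coh <- toy_cohort()
  bal <- iv_balance(coh, "iv")
  expect_equal(bal$prev_treated, 4 / 5)
  expect_equal(bal$prev_comparison, 1 / 5)
  expect_error(iv_balance(coh, "x1"), regexp = "dichotomize",
               class = "acce_input_error")
})

test_that("stratified balance is near-perfect when the score fully captures the IV", {
  # score built on the IV itself: within strata the IV is (nearly) constant
  set.seed(31)
  n <- 4000
  z <- rbinom(n, 1, 0.5)
  p <- 0.3 + 0.4 * z
  df <- data.frame(treatment = rbinom(n, 1, p),
                   outcome = rbinom(n, 1, 0.1),
                   x1 = rnorm(n), iv = z)
  coh <- as_cohort(df, iv_columns = "iv")
  fit <- fit_linear_ps(coh, c("x1", "iv"))
  bal <- iv_balance(coh, "iv", fit, n_strata = 10)
  expect_lt(abs(bal$prev_treated - bal$prev_comparison), 0.05)
  raw <- iv_balance(coh, "iv")
  expect_gt(raw$prev_treated - raw$prev_comparison, 0.3)
})

test_that("internal marker ratio is 1 when Model 2 equals Model 1", {
  coh <- suppressWarnings(generate_cohort(sim_scenario(n = 30000, seed = 3)))
  spec <- nested_model_spec("conf_measured", character(), withheld_marker = "u1")
  expect_warning(r <- internal_marker_amplification(coh, spec),
                 regexp = "underestimate")
  expect_equal(as.numeric(r), 1.0, tolerance = 1e-8)
})

test_that("internal marker tracks the realized between-model amplification", {
  sc <- sim_scenario(n = 100000, seed = 77)
  coh <- suppressWarnings(generate_cohort(sc))
  spec <- nested_model_spec("conf_measured", "iv", withheld_marker = "u1")
  r <- suppressWarnings(internal_marker_amplification(coh, spec))
  # the R^2-law ratio here is about 1.14; the realized amplification the
  # marker sees is somewhat larger
  expect_gt(as.numeric(r), 1.05)
  expect_lt(as.numeric(r), 1.40)
})

test_that("a marker exactly balanced under Model 1 is an undefined ratio", {
  # mirror construction: every subject duplicated with treatment flipped,
  # so all covariates (incl. the marker) are exactly balanced
  set.seed(11)
  n <- 50
  base <- data.frame(x1 = rnorm(n), iv = rbinom(n, 1, 0.5), marker = rnorm(n))
  df <- rbind(cbind(base, treatment = 1L), cbind(base, treatment = 0L))
  df <- df[rep(seq_len(n), each = 2) + c(0, n), ]
  df$outcome <- rbinom(2 * n, 1, 0.2)
  coh <- as_cohort(df, iv_columns = "iv")
  spec <- nested_model_spec("x1", "iv", withheld_marker = "marker", n_strata = 10)
  expect_error(suppressWarnings(internal_marker_amplification(coh, spec)),
               class = "acce_domain_error")
})
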