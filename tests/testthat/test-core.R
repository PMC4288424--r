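# Core summary-equation arithmetic: amplification algebra, Bross terms,
# the back-extrapolation, and the classed error contracts.

test_that("model_amplification reproduces the worked multipliers and is monotone", {
  expect_equal(model_amplification(0.5), 2.0)
  expect_equal(model_amplification(0.25), 1 / 0.75)
  expect_equal(model_amplification(0), 1.0)
  r2 <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(model_amplification(r2)) > 0))
  expect_true(all(model_amplification(r2) >= 1))
  expect_error(model_amplification(1), class = "acce_domain_error")
  expect_error(model_amplification(-0.1), class = "acce_domain_error")
})

test_that("amplification_increment matches both algebraic forms and the worked value", {
  expect_equal(amplification_increment(0.25, 0.5), 0.5)
  # ratio form and difference form agree across a grid
  for (r1 in c(0, 0.04, 0.3, 0.56)) {
    for (r2 in c(0.05, 0.4, 0.56, 0.9)) {
      expect_equal(amplification_increment(r1, r2),
                   (r2 - r1) / (1 - r2), tolerance = 1e-12)
    }
  }
  expect_equal(amplification_increment(0.04, 0.56), (0.56 - 0.04) / (1 - 0.56))
  for (r in c(0, 0.2, 0.7)) expect_equal(amplification_increment(r, r), 0)
  expect_error(amplification_increment(0.5, 0.25, require_positive = TRUE),
               class = "acce_extrapolation_error")
})

test_that("bross_log_confounding matches direct bias-factor arithmetic", {
  expect_equal(round(bross_log_confounding(0.80, 0.20, 1.05), 4), 0.0293)
  expect_equal(bross_log_confounding(0.52, 0.48, 1.05),
               log(1.026 / 1.024), tolerance = 1e-12)
  # zero at balance or null association
  expect_equal(bross_log_confounding(0.3, 0.3, 2.2), 0)
  expect_equal(bross_log_confounding(0.9, 0.1, 1.0), 0)
  # antisymmetry under swapping arms, sign from imbalance x association
  set.seed(41)
  for (i in 1:50) {
    pt <- runif(1); pc <- runif(1); rr <- exp(runif(1, -1, 1))
    v <- bross_log_confounding(pt, pc, rr)
    expect_equal(bross_log_confounding(pc, pt, rr), -v, tolerance = 1e-12)
    expect_equal(sign(v), sign(rr - 1) * sign(pt - pc))
  }
  expect_error(bross_term(1.2, 0.5, 1.1), class = "acce_domain_error")
  expect_error(bross_term(0.5, 0.5, -1), class = "acce_domain_error")
})

test_that("delta_iv_confounding gives the worked rebalancing change and guards rr mismatch", {
  d <- delta_iv_confounding(bross_term(0.80, 0.20, 1.05),
                            bross_term(0.52, 0.48, 1.05))
  expect_equal(round(d, 4), -0.0273)
  expect_equal(delta_iv_confounding(bross_term(0.6, 0.3, 1.4),
                                    bross_term(0.6, 0.3, 1.4)), 0)
  expect_equal(delta_iv_confounding(bross_term(0.8, 0.2, 1.0),
                                    bross_term(0.5, 0.5, 1.0)), 0)
  expect_error(delta_iv_confounding(bross_term(0.8, 0.2, 1.05),
                                    bross_term(0.5, 0.5, 1.06)),
               class = "acce_input_error")
})

test_that("adjusted_delta_tee and amplifiable_confounding reproduce the worked chains", {
  d <- delta_iv_confounding(bross_term(0.80, 0.20, 1.05),
                            bross_term(0.52, 0.48, 1.05))
  adj <- adjusted_delta_tee(0.235072, 0.2612, d)
  expect_equal(round(adj, 4), 0.0534)
  expect_equal(adjusted_delta_tee(0.09531, 0.142965, 0), 0.047655)
  expect_equal(adjusted_delta_tee(0.3, 0.3, 0), 0)
  expect_equal(round(amplifiable_confounding(0.0534, 0.25, 0.5), 4), 0.1068)
  expect_equal(amplifiable_confounding(0.047655, increment = 0.5), 0.09531)
  expect_equal(amplifiable_confounding(0, 0.1, 0.3), 0)
  expect_error(amplifiable_confounding(0.05, 0.5, 0.5),
               class = "acce_extrapolation_error")
  expect_error(amplifiable_confounding(0.05, increment = -0.2),
               class = "acce_extrapolation_error")
})

test_that("|amplifiable_confounding| decreases as the increment grows", {
  incs <- c(0.1, 0.25, 0.5, 1, 2)
  vals <- sapply(incs, function(i) abs(amplifiable_confounding(0.06, increment = i)))
  expect_true(all(diff(vals) < 0))
})

test_that("unconfounded_tee reproduces the worked examples end to end", {
  # IV with outcome association, full chain
  ex4 <- unconfounded_tee(example_fixture(4))
  expect_lt(abs(ex4$unconfounded_tee - 0.09903), 0.0005)
  expect_lt(abs(ex4$amplifiable_confounding - 0.1068), 0.0005)
  expect_lt(abs(ex4$total_residual_confounding - 0.1361), 0.0005)
  # true-instrument variant
  ex3 <- unconfounded_tee(example_fixture(3))
  expect_lt(abs(ex3$unconfounded_tee - 0.1829), 0.0005)
  # entire Model 1 effect explained by confounding
  ex1 <- unconfounded_tee(example_fixture(1))
  expect_equal(ex1$unconfounded_tee, 0, tolerance = 1e-10)
  expect_equal(ex1$amplifiable_confounding, 0.09531, tolerance = 1e-10)
  # unchanged estimate: no residual confounding at all
  ex2 <- unconfounded_tee(example_fixture(2))
  expect_equal(ex2$unconfounded_tee, 0.09531, tolerance = 1e-12)
  expect_equal(ex2$total_residual_confounding, 0, tolerance = 1e-12)
  # identity: k = TEE_M1 - total residual confounding, by construction
  expect_equal(ex4$unconfounded_tee,
               ex4$inputs$tee_m1 - ex4$total_residual_confounding)
})

test_that("unconfounded_tee flags R^2 outside the simulation-supported band", {
  flagged <- unconfounded_tee(acce_inputs(0.1, 0.15, 0.02, 0.70))
  expect_true(any(grepl("R\\^2", flagged$warnings)))
  clean <- unconfounded_tee(acce_inputs(0.1, 0.15, 0.25, 0.50))
  expect_length(clean$warnings, 0)
})

test_that("forward-constructed effect pairs are inverted exactly", {
  # forward model: tee_m1 = x + y + k, tee_m2 = ratio*x + y2 + k with
  # conf terms y2 - y and y; inversion must recover x and k
  set.seed(7)
  for (i in 1:200) {
    x <- runif(1, -0.3, 0.3)
    y1 <- runif(1, -0.1, 0.1)
    y2 <- runif(1, -0.1, 0.1)
    k <- runif(1, -0.5, 0.5)
    r2_m1 <- runif(1, 0, 0.8)
    r2_m2 <- runif(1, r2_m1 + 0.01, 0.9)
    ratio <- model_amplification(r2_m2) / model_amplification(r2_m1)
    res <- unconfounded_tee(acce_inputs(
      tee_m1 = x + y1 + k,
      tee_m2 = ratio * x + y2 + k,
      r2_m1 = r2_m1, r2_m2 = r2_m2,
      conf_iv_delta = y2 - y1, conf_iv_m1 = y1
    ))
    expect_equal(res$amplifiable_confounding, x, tolerance = 1e-12)
    expect_equal(res$unconfounded_tee, k, tolerance = 1e-12)
  }
})

test_that("domain and input errors carry their declared classes", {
  expect_error(acce_inputs(0.1, NA, 0.2, 0.5), class = "acce_input_error")
  expect_error(acce_inputs(0.1, 0.2, 1.0, 0.5), class = "acce_domain_error")
  expect_error(unconfounded_tee(list(tee_m1 = 1)), class = "acce_input_error")
  expect_error(unconfounded_tee(acce_inputs(0.1, 0.2, 0.5, 0.5)),
               class = "acce_extrapolation_error")
})
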