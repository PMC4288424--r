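---
title: "Estimating total residual confounding by deliberate amplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating total residual confounding by deliberate amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acce)
```

## The model

A nonrandomized comparison of a binary treatment `T` on a binary outcome
`Y` carries residual confounding from everything the propensity model
omits. Write the Model 1 treatment effect estimate, on the natural-log
risk-ratio (beta) scale, as

    TEE_M1 = x + y + k

where `k` is the genuine treatment effect, `y` is the confounding
contributed by a deliberately **Introduced Variable** (a covariate left
out of Model 1 and added to form Model 2, chosen because it strongly
predicts exposure), and `x` is confounding from everything absent from
*both* models — the **amplifiable fraction**. Conditioning on a
propensity score amplifies `x`: for a linear-probability score with
coefficient of determination `R²`, residual confounding is multiplied by
`1/(1 − R²)`. Between two nested models the amplification ratio is
`(1 − R²_M1)/(1 − R²_M2)`, so

    TEE_M2 = ratio · x + y' + k

with `y'` the Introduced Variable's (reduced) confounding once it is
inside the Model 2 score. Subtracting the two equations, adjusting the
observed change by `y' − y` (estimated via the Bross bias formula), and
dividing by `ratio − 1` isolates `x`; adding `y` and subtracting the
total from `TEE_M1` yields the unconfounded estimate `k`. `y` and `y'`
are estimated by combining the Introduced Variable's outcome regression
coefficient with its arm-specific prevalences through the Bross formula
`ln[(1 + p_t(RR − 1))/(1 + p_c(RR − 1))]`.

The identity is exact given the forward model — the package verifies
inversion to `1e-12` over random draws — so all scientific risk lives in
the premises: (i) amplification really is proportional to `1/(1 − R²)`,
(ii) the regression coefficient captures the Introduced Variable's
confounding, (iii) nothing else changes between the models, and (iv) `k`
itself is invariant to the conditioning. These are discussed as
limitations below.

### Assumptions inherited by every analysis

* Outcomes follow a risk-ratio (log-link) model; hazard ratios and odds
  ratios are out of scope because their noncollapsibility breaks the
  additive decomposition above.
* Propensity models are linear-probability OLS fits: the `1/(1 − R²)`
  relation is established for linear R² only. Logistic pseudo-R² and c
  statistics have no known calibration to amplification and are
  deliberately unsupported.
* The linearity of amplification in `1 − R²` has simulation support for
  R² between 0.04 and 0.56; results outside that band carry a warning.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_strata` | 10 | strata | conventional quantile stratification; deterministic, unlike matching |
| `m1_balance` | `"stratified"` | — | the Bross terms should use the balance Model 1 *achieves*, i.e. within its own score strata; `"raw"` is available |
| `min_increment` | 0.01 | fraction | Model 2 nests Model 1, so the in-sample R² difference is never negative; below 1% extra amplification the back-extrapolation divides by sampling noise and is refused |
| `known_instrument` | `FALSE` | — | when the Introduced Variable is known to have no outcome association, the outcome-coefficient step is skipped entirely (see below) |
| probe thresholds | 0.01 / 0.05 | beta | a between-model shift below 0.01 reads as no change, below 0.05 as small, else sizeable; brackets the published nested-pair illustrations (shifts of ≈0.024 and ≈0.097) |
| bootstrap | percentile, by subject | — | percentile intervals are the auditable baseline; arm-stratified resampling is optional |

Quantile strata use rank order with stable first-occurrence tie-breaking,
so stratification is deterministic and seed-free; a constant score
collapses to a single stratum (the crude estimate). Strata missing an arm
are dropped with a warning; Mantel–Haenszel weights pool the rest. If a
log-binomial outcome regression fails to converge, a linear-risk fit with
delta-method conversion to log-RR is used and flagged in the result.

## Why `known_instrument` exists

Estimating the Introduced Variable's outcome coefficient when its true
value is zero is not harmless. The within-arm regressions condition on
treatment, which induces a collider association between the Introduced
Variable and any unmeasured confounder (both raise the probability of the
arm one is in); the same happens when treatment enters a pooled
regression as a covariate. In simulations with a true-instrument
Introduced Variable the estimated coefficient is systematically non-zero
(≈ −0.02 under the default validation scenario), and the Bross terms
leverage that artifact two- to three-fold into the final estimate. When
the analyst *knows* the variable is an instrument, the correct procedure
is the short path: back-extrapolate and skip the adjustment. The full
estimation path remains the default for the realistic case where the
outcome association is unknown, and its artifact is one of the method's
acknowledged open problems (it grows with the product of the Introduced
Variable's exposure weight and the unmeasured confounding strength).

## What the simulator emulates

`sim_scenario()` generates the minimal structure the method needs to be
tested against: one measured gaussian confounder, one binary Introduced
Variable (gaussian-copula latent, so it can be correlated with the first
unmeasured confounder), one or two gaussian unmeasured confounders,
treatment drawn from a linear-probability index, and outcome drawn from a
log-risk index containing the genuine effect `k`. Defaults: `n = 50000`,
`k = log(1.10)`, baseline risk 0.10, measured confounder weights
(exposure 0.17, outcome log-RR 0.20), Introduced Variable exposure weight
0.34 with no outcome association, one unmeasured confounder (exposure
0.07, outcome log-RR 0.15 — residual confounding of roughly beta 0.05,
an RR-1.05-sized bias), no Introduced-Variable–confounder correlation.

Two generator properties deserve emphasis:

* **Probability clipping bounds attainable R².** Treatment probabilities
  are clipped to [0.02, 0.98]. A clipped linear-probability index with
  mean 0.5 cannot produce a fitted R² of 0.5 without clipping well over a
  quarter of subjects (the generator treats >25% as a misspecified
  scenario and errors; >5% warns). The analytic worked examples' R² pair
  0.25/0.5 is therefore not reachable inside the generator; the defaults
  were calibrated with `calibrate_scenario()` to fitted R² ≈ 0.10/0.21 at
  under 5% clipping. This is a deliberate choice: the `1/(1 − R²)` law is
  exact (to first order) only while the linear-probability model actually
  holds, and our own grid experiments show the law under-predicting
  realized amplification by 30–70% once 17–27% of subjects are clipped.
* **Determinism.** A scenario seed fully determines the cohort;
  `recovery_experiment()` derives per-replicate seeds by a fixed counter
  (`seed + replicate index`), so experiments are reproducible and
  trivially parallelizable.

What the simulator does **not** emulate: correlated measured covariates,
real-world "constraints" on amplification, treatment-effect
heterogeneity, post-initiation confounding, time-to-event outcomes, and
measurement error. Passing recovery tests therefore show that the
implementation inverts its own generative assumptions — not that the
method is accurate on real data, which remains an open question.

## Numerical choices and degenerate inputs

* All internal arithmetic on the log-RR scale; RRs converted at the
  interfaces. Reports serialize full precision plus a 4-decimal display
  block (matching the worked examples' reporting convention).
* Bross terms require a binary covariate; continuous Introduced
  Variables must be dichotomized by the user (explicit error).
* Several Introduced Variables are handled additively: Bross terms per
  variable from marginal balances, summed, flagged in the output.
* An Introduced Variable constant within an arm falls back to a pooled
  outcome regression with a treatment indicator (warning).
* Errors are classed (`acce_domain_error`, `acce_extrapolation_error`,
  `acce_input_error`, `acce_estimation_error`, `acce_inference_error`) so
  the bootstrap can count recoverable failures: replicates failing the
  minimum-increment guard are dropped and counted, and more than 20%
  failures aborts with a breakdown.
* Bootstrap intervals are percentile; the point estimate occasionally
  falls outside a heavily skewed interval, which is flagged rather than
  treated as an error.

## Validation studies shipped in the test suite

The test suite runs, besides unit oracles, two scaled-down Monte-Carlo
studies chosen to fit comfortably in a routine test run: parameter
recovery (200 replicates of the default true-instrument scenario at
n = 50,000, mean unconfounded estimate within ±0.02 of the genuine
`k = 0.09531`) and bootstrap coverage under the null (100 replications of
B = 150 percentile intervals at n = 12,000, empirical 95% coverage
required to land in [0.90, 0.99]; a development run of 150 replications
gave 0.94). The internal-marker estimator is checked against the realized
amplification on the same scenarios.

## Known limitations

* The residual recovery bias of the full pipeline (collider artifact in
  the outcome coefficient, stratification coarseness, clipping) is small
  under the default scenario but grows with confounding strength and with
  Introduced-Variable exposure weight; the method's quantitative accuracy
  on real data is unestablished.
* Between-model changes in the balance of *measured* covariates are not
  Bross-corrected (they are second-order under fine stratification but
  measurable: in our experiments the measured confounder's within-stratum
  imbalance grows when the bimodal Model 2 score is coarsely stratified).
* The back-extrapolation explodes as the amplification increment shrinks;
  the `min_increment` guard refuses such analyses rather than returning a
  noise-dominated number.
* Only percentile bootstrap intervals are offered; no analytic variance.
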