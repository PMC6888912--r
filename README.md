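# jmsim

Simulation-based robustness assessment of **joint models** versus the
**time-varying covariate Cox model (TVCM)** for estimating the
association between a longitudinal biomarker and a time-to-event
endpoint.

## The problem

A biomarker measured repeatedly during follow-up (weekly, say, after a
transplant) may drive the hazard of a clinical event. The standard
analysis is the TVCM,

> h_i(t) = h0(t) · exp{ α · y_i(t) },

which carries the last observed marker value forward (LOCF) and treats it
as measured without error; α is the log hazard ratio per marker unit and
inference uses the Cox partial likelihood with an unspecified h0. The
alternative is the shared-random-effects **joint model**: a linear mixed
model for the marker trajectory,

> y_i(t) = βᵀf(t) + b_iᵀg(t) + ε_i(t),  b_i ~ N(0, Σ),  ε ~ N(0, σ_ε²),

linked to the proportional-hazards submodel h_i(t) = h0(t)·exp{α·w_i(t)}
through the *true* current value w_i(t) = βᵀf(t) + b_iᵀg(t), with h0
specified parametrically (constant, Weibull λρt^(ρ−1)) or as a B-spline
log hazard. The joint model removes the LOCF and measurement-error biases
of the TVCM but is sensitive to misspecification of the random-effects
distribution, the trajectory shape and the baseline hazard.

`jmsim` provides, in one tested package:

* a **synthetic-cohort generator** (`scenario_preset()`,
  `simulate_cohort()`): polynomial trajectories with normal or
  non-normal random effects, Gaussian measurement error, event times by
  inverse-cumulative-hazard root finding under Weibull or non-monotonic
  baselines, uniform (0, 14) plus administrative week-14 censoring;
* **from-scratch estimators**: the counting-process Cox partial
  likelihood with Efron ties (`expand_locf()`, `fit_cox()`), a two-stage
  mixed-model-then-Cox estimator (`two_stage_fit()`), and full maximum
  likelihood for the joint model with pseudo-adaptive Gauss–Hermite
  integration over the random effects (`fit_joint()`,
  `marginal_survival()`);
* a **Monte-Carlo harness** (`run_scenario()`, `summarize_metrics()`,
  `exclusion_filter()`) reporting Est, ESE, ASE, bias, %bias, 95%
  coverage and MSE per scenario cell, with convergence and outlier
  bookkeeping, plus YAML/JSON-config driven runs (`run_from_config()`).

## Worked example

Simulate one cohort of 300 subjects under the linear-trajectory scenario
with large measurement error (σ_ε = 0.5), then estimate the association
(true α = 0.3) both ways:

```r
library(jmsim)
sp     <- scenario_preset(2, n = 300, alpha = 0.3, sigma_eps = 0.5)
cohort <- simulate_cohort(sp, seed = 7)
cohort
#> Simulated cohort: 300 subjects, 807 measurements, 78.0% events

tvcm <- fit_cox(expand_locf(cohort$longitudinal, cohort$survival))
tvcm
#> Cox partial-likelihood fit
#>   alpha = 0.2939 (se 0.0488), HR = 1.342
#>   loglik = -1089.8547, 3 iterations, converged: TRUE

joint <- fit_joint(cohort$longitudinal, cohort$survival, baseline = "weibull")
joint
#> Joint model fit ( weibull baseline )
#>   alpha = 0.3229 (se 0.0491), HR = 1.381 (95% CI 1.254, 1.521)
#>   loglik = -1493.018
```

On this single cohort both estimates are within sampling error of the
truth; the systematic difference appears across replicates: the TVCM
estimate is attenuated by the noise in `y` while the joint model, which
integrates over the measurement error, stays centred near 0.3. A
Monte-Carlo cell makes that visible:

```r
res <- run_scenario(sp, B = 100, models = c("tvcm_1x", "joint_weibull"),
                    alpha = 0.3, sigma_eps = 0.5, seed = 1)
res[, c("model", "Est", "ESE", "ASE", "PctBias", "CP")]
```

Columns: `Est` mean estimate, `ESE` SD of the estimates, `ASE` mean
reported SE, `PctBias` = 100·(Est − α)/α, `CP` the fraction of Wald 95%
intervals covering α.

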