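test_that("spline log-hazard basis has the contracted knots and unity sum", {
  obs <- 1:99
  B <- spline_log_hazard_basis(obs, t = c(10, 33, 50, 72, 90), 5)
  expect_equal(attr(B, "knots"),
               quantile(obs, (1:5) / 6, names = FALSE))
  # partition of unity at interior points
  expect_equal(rowSums(B), rep(1, 5), tolerance = 1e-12)
  # all gamma = 0 means h0 = 1 everywhere
  expect_equal(exp(drop(B %*% rep(0, ncol(B)))), rep(1, 5))
  # clamped beyond the boundary
  Bhi <- spline_log_hazard_basis(obs, t = 150, 5)
  Bend <- spline_log_hazard_basis(obs, t = 99, 5)
  expect_equal(as.numeric(Bhi), as.numeric(Bend))
  expect_equal(ncol(B), 5 + 3 + 1)
})

test_that("mixed-model stage recovers the generating longitudinal model", {
  # noiseless, no random effects: exact regression coefficients
  tt <- rep(0:14, 20)
  long0 <- data.frame(id = rep(1:20, each = 15), time = tt,
                      y = 3.2 - 0.07 * tt)
  f0 <- fit_lmm(long0)
  expect_equal(f0$beta, c(3.2, -0.07), tolerance = 1e-8)
  expect_lt(f0$sigma, 1e-6)
  expect_true(all(diag(f0$Sigma) < 1e-6))
  # alpha = 0 cohort (no informative event truncation of the visits):
  # estimates near the generator truth
  co0 <- simulate_cohort(scenario_preset(2, n = 300, alpha = 0,
                                         sigma_eps = 0.3), seed = 1201)
  f <- fit_lmm(co0$longitudinal)
  expect_lt(abs(f$beta[1] - 3.2), 2 * sqrt(1.44 / 300) + 0.02)
  expect_lt(abs(f$beta[2] + 0.07), 2 * sqrt(0.04 / 300) + 0.01)
  expect_lt(abs(f$sigma / 0.3 - 1), 0.05)
  expect_lt(abs(f$Sigma[1, 1] / 1.44 - 1), 0.25)
  # under alpha > 0 the event truncation biases the marker-only fit a
  # little (high-marker subjects drop out early); sanity band only
  co <- s2_cohort()
  fs <- fit_lmm(co$longitudinal)
  expect_lt(abs(fs$beta[1] - 3.2), 0.3)
  expect_lt(abs(fs$beta[2] + 0.07), 0.06)
  # empirical-Bayes prediction works per subject
  w <- predict_trajectory(fs, co$survival$id[1], c(0, 7))
  expect_length(w, 2)
  expect_true(all(is.finite(w)))
})

test_that("random-intercept variance is recovered at larger n", {
  co <- simulate_cohort(scenario_preset(6, n = 600, sigma_eps = 0.3),
                        seed = 4242)
  f <- fit_lmm(co$longitudinal, random = "intercept")
  expect_lt(abs(f$Sigma[1, 1] / 1.44 - 1), 0.10)
})

test_that("conditional subject log-likelihood matches direct formulas", {
  hz <- baseline_hazard_spec("weibull", 0.1, 1.4)
  # single baseline measurement at the true mean: Gaussian density term
  ll <- subject_loglik_given_b(y = 3.2, times = 0, t_obs = 1e-9, status = 0,
                               b = c(0, 0), beta = c(3.2, 0),
                               sigma_eps = 0.1, hazard = hz, alpha = 0.3)
  expect_equal(ll, log(1 / (0.1 * sqrt(2 * pi))), tolerance = 1e-6)
  # censored subject without measurements contributes only -H(T)
  ll2 <- subject_loglik_given_b(numeric(0), numeric(0), t_obs = 5, status = 0,
                                b = c(0, 0), beta = c(3.2, 0),
                                sigma_eps = 0.1, hazard = hz, alpha = 0.3)
  expect_equal(ll2, -0.1 * 5^1.4 * exp(0.3 * 3.2), tolerance = 1e-8)
  # event subject, constant marker: survival part matches the closed form
  ll3 <- subject_loglik_given_b(numeric(0), numeric(0), t_obs = 5, status = 1,
                                b = c(0, 0), beta = c(3.2, 0),
                                sigma_eps = 0.1, hazard = hz, alpha = 0.3)
  H <- integrate(function(s) baseline_hazard(hz, s) * exp(0.3 * 3.2), 0, 5,
                 rel.tol = 1e-12)$value
  expect_equal(ll3, log(baseline_hazard(hz, 5)) + 0.3 * 3.2 - H,
               tolerance = 1e-6)
})

test_that("Gauss-Hermite marginal likelihood matches Monte-Carlo integration", {
  # pseudo-adaptive centering: the subject posteriors are much narrower
  # than the random-effects law, which fixed-node standard quadrature
  # cannot resolve - the adaptive rule is the one the fitter uses. The
  # stage-1 centers come from the full cohort; the marginal likelihood is
  # evaluated on a 3-subject subset against plain Monte-Carlo integration.
  co <- simulate_cohort(scenario_preset(2, n = 300, sigma_eps = 0.3),
                        seed = 314)
  lmm <- fit_lmm(co$longitudinal)
  long3 <- co$longitudinal[co$longitudinal$id %in% 1:3, ]
  surv3 <- co$survival[co$survival$id %in% 1:3, ]
  params <- list(beta = c(3.2, -0.07), Sigma = diag(c(1.44, 0.04)),
                 sigma_eps = 0.3, gamma = c(0.1, 1.4), alpha = 0.3)
  gh <- marginal_loglik(long3, surv3, params,
                        center = "pseudo-adaptive", lmm = lmm)
  mc <- mc_marginal_loglik(long3, surv3, params,
                           baseline_hazard_spec("weibull", 0.1, 1.4),
                           n_draws = 1e6, seed = 2718)
  expect_equal(gh, mc, tolerance = 1e-3)
})

test_that("marginal likelihood collapses to the conditional as Sigma -> 0", {
  sp <- scenario_preset(2, n = 5, sigma_eps = 0.3)
  co <- simulate_cohort(sp, seed = 11)
  hz <- baseline_hazard_spec("weibull", 0.1, 1.4)
  params <- list(beta = c(3.2, -0.07), Sigma = diag(c(1e-10, 1e-10)),
                 sigma_eps = 0.3, gamma = c(0.1, 1.4), alpha = 0.3)
  marg <- marginal_loglik(co$longitudinal, co$survival, params,
                          center = "standard")
  cond <- sum(vapply(co$survival$id, function(id) {
    rows <- co$longitudinal$id == id
    subject_loglik_given_b(co$longitudinal$y[rows],
                           co$longitudinal$time[rows],
                           co$survival$time[co$survival$id == id],
                           co$survival$status[co$survival$id == id],
                           b = c(0, 0), beta = params$beta,
                           sigma_eps = 0.3, hazard = hz, alpha = 0.3)
  }, numeric(1)))
  expect_equal(marg, cond, tolerance = 1e-6)
})

test_that("marginal likelihood is stable in the number of quadrature nodes", {
  co <- s2_cohort()
  long <- co$longitudinal[co$longitudinal$id <= 150, ]
  surv <- co$survival[co$survival$id <= 150, ]
  lmm <- fit_lmm(long)
  params <- list(beta = lmm$beta, Sigma = jmsim:::ensure_pd(lmm$Sigma),
                 sigma_eps = lmm$sigma, gamma = c(0.1, 1.4), alpha = 0.3)
  lls <- vapply(c(9, 15, 21), function(k) {
    marginal_loglik(long, surv, params, gh_nodes = k,
                    center = "pseudo-adaptive", lmm = lmm)
  }, numeric(1))
  expect_lt(max(abs(diff(lls))), 1e-4 * abs(lls[1]))
})

test_that("joint fit recovers the generating parameters on scenario-2 data", {
  co <- s2_cohort()
  fit <- fit_joint(co$longitudinal, co$survival, baseline = "weibull")
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-3)
  # each parameter within sampling distance of the truth (single cohort)
  expect_lt(abs(fit$alpha - 0.3), 3 * fit$alpha_se)
  expect_lt(abs(fit$beta[1] - 3.2), 3 * fit$beta_se[1])
  expect_lt(abs(fit$beta[2] + 0.07), 3 * fit$beta_se[2])
  expect_lt(abs(fit$sigma_eps - 0.3), 0.02)
  expect_lt(abs(fit$Sigma[1, 1] / 1.44 - 1), 0.3)
  # loglik at the optimum beats the true generating parameters
  truth <- list(beta = c(3.2, -0.07), Sigma = diag(c(1.44, 0.04)),
                sigma_eps = 0.3, gamma = c(0.1, 1.4), alpha = 0.3)
  ll_truth <- marginal_loglik(co$longitudinal, co$survival, truth,
                              center = "pseudo-adaptive", lmm = fit$lmm)
  expect_gte(fit$loglik + 1e-6, ll_truth)
  # reported SE is positive and the HR is exp(alpha)
  expect_gt(fit$alpha_se, 0)
})

test_that("marginal survival is a proper, calibrated survival curve", {
  co <- s2_cohort()
  fit <- fit_joint(co$longitudinal, co$survival, baseline = "weibull")
  times <- seq(0, 14, by = 0.5)
  S <- marginal_survival(fit, times)
  expect_equal(S[1], 1)
  expect_true(all(diff(S) <= 1e-12))
  expect_true(all(S >= 0 & S <= 1))
  # against the latent event times of a large fresh cohort
  big <- simulate_cohort(scenario_preset(2, n = 1e4, sigma_eps = 0.3),
                         seed = 5150)
  emp <- vapply(times, function(t) mean(big$latent$t_star > t), numeric(1))
  expect_lt(max(abs(S - emp)), 0.02)
})

test_that("alpha = 0 marginal survival equals the baseline survival", {
  co <- simulate_cohort(scenario_preset(2, n = 200, alpha = 0), seed = 808)
  fit <- fit_joint(co$longitudinal, co$survival, baseline = "weibull")
  # with the fitted alpha free this only holds approximately; force alpha 0
  fit$alpha <- 0
  times <- c(0, 2, 5, 10, 14)
  S <- marginal_survival(fit, times)
  expect_equal(S, exp(-fit$gamma[1] * times^fit$gamma[2]), tolerance = 1e-6)
})

test_that("non-convergence is reported via flags, not errors", {
  # two subjects cannot support a joint fit; expect a graceful flag
  co <- simulate_cohort(scenario_preset(2, n = 2), seed = 99)
  fit <- suppressWarnings(fit_joint(co$longitudinal, co$survival))
  expect_s3_class(fit, "joint_fit")
  expect_false(isTRUE(fit$converged) && is.na(fit$alpha))
})
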