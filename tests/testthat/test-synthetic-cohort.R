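test_that("spec constructors validate their inputs", {
  expect_error(random_effects_spec("chisquare", c(1.44, 0.04)),
               "random-intercept only")
  expect_error(random_effects_spec("normal", c(-1, 0)), ">= 0")
  expect_error(baseline_hazard_spec("weibull", lambda = -1), "lambda > 0")
  expect_error(scenario_spec(schedule = c(1, 2)), "start at t = 0")
  expect_error(scenario_spec(schedule = c(0, 2, 1)), "strictly increasing")
  expect_error(scenario_spec(schedule = c(0, 20)), "admin_time")
  expect_error(scenario_spec(sigma_eps = -0.1), "sigma_eps")
})

test_that("mean trajectory at t = 0 is exactly beta0 and evaluation is exact", {
  tr <- trajectory_spec(3.2, -0.16, 0.01)
  expect_identical(true_trajectory(tr, times = 0), 3.2)
  expect_equal(true_trajectory(trajectory_spec(3.2), times = 7), 3.2)
  expect_equal(true_trajectory(trajectory_spec(3.2, -0.07), times = 14), 2.22)
  expect_equal(true_trajectory(tr, times = 10), 2.6)
  # random effects shift each polynomial coefficient
  expect_equal(true_trajectory(tr, b = c(1, 0.5, -0.01), times = 2),
               (3.2 + 1) + (-0.16 + 0.5) * 2 + 0 * 4)
})

test_that("degenerate normal effects are exactly zero", {
  spec <- random_effects_spec("normal", c(0, 0))
  b <- draw_random_effects(spec, 5)
  expect_identical(dim(b), c(5L, 2L))
  expect_true(all(b == 0))
})

test_that("drawn effects match the analytic moments of each family", {
  n <- 1e6
  fams <- list(
    normal = random_effects_spec("normal", 1.44),
    chisquare = random_effects_spec("chisquare", 1.44),
    gamma = random_effects_spec("gamma", 1.44),
    bimodal = random_effects_spec("bimodal", 1.44))
  # closed-form variances: 1.44, 2*0.72, 0.5*1.7^2, and the mixture's
  # 1.44 + 0.65*0.35*(15-8)^2
  target <- c(normal = 1.44, chisquare = 1.44, gamma = 1.445,
              bimodal = 1.44 + 0.65 * 0.35 * 49)
  set.seed(41)
  for (nm in names(fams)) {
    b <- draw_random_effects(fams[[nm]], n)[, 1]
    expect_lt(abs(var(b) / target[[nm]] - 1), 0.01)
    expect_lt(abs(mean(b)), 3 * sqrt(target[[nm]] / n))
  }
})

test_that("measurement error has the configured spread and zero-noise is exact", {
  w <- rep(3.2, 1e6)
  expect_identical(observe_marker(w, 0), w)
  expect_error(observe_marker(w, -0.1), ">= 0")
  set.seed(7)
  y <- observe_marker(w, 0.3)
  expect_lt(abs(sd(y - w) / 0.3 - 1), 0.01)
  # coefficients of variation at the baseline marker level
  expect_identical(round(100 * c(0.1, 0.3, 0.5) / 3.2, 1), c(3.1, 9.4, 15.6))
})

test_that("baseline hazards follow their closed forms", {
  wb <- baseline_hazard_spec("weibull", 0.1, 1.4)
  expect_equal(baseline_hazard(wb, 1), 0.14)
  expect_error(baseline_hazard(wb, -1), "t < 0")
  # rho = 1 reduces to a constant hazard
  expect_equal(baseline_hazard(baseline_hazard_spec("weibull", 0.1, 1),
                               c(0, 1, 7)), rep(0.1, 3))
  nm <- baseline_hazard_spec("nonmonotonic", nu = 1, kappa = 2, c = 10)
  expect_equal(baseline_hazard(nm, 2), 4 / 14)
  # rises from 0, peaks near sqrt(10), then decays
  grid <- seq(0, 14, by = 0.01)
  h <- baseline_hazard(nm, grid)
  expect_equal(h[1], 0)
  pk <- which.max(h)
  expect_equal(grid[pk], sqrt(10), tolerance = 0.01)
  expect_equal(h[pk], sqrt(10) / 10, tolerance = 1e-4)
  expect_true(all(diff(h[1:pk]) > 0))
  expect_true(all(diff(h[pk:length(h)]) < 0))
})

test_that("cumulative hazard matches quadrature oracles and is zero at 0", {
  wb <- baseline_hazard_spec("weibull", 0.1, 1.4)
  tr <- trajectory_spec(3.2)
  expect_identical(cumulative_hazard(wb, 0.3, tr, t = 0), 0)
  expect_equal(cumulative_hazard(wb, 0.3, tr, t = 5),
               0.1 * 5^1.4 * exp(0.3 * 3.2), tolerance = 1e-8)
  nm <- baseline_hazard_spec("nonmonotonic")
  expect_equal(cumulative_hazard(nm, 0, tr, t = 5), log(3.5), tolerance = 1e-8)
  # non-constant marker: compare against independent adaptive quadrature
  tr2 <- trajectory_spec(3.2, -0.07)
  b <- c(0.5, 0.1, 0)
  oracle <- integrate(function(s) baseline_hazard(wb, s) *
                        exp(0.3 * true_trajectory(tr2, b, s)),
                      0, 8, rel.tol = 1e-12)$value
  expect_equal(cumulative_hazard(wb, 0.3, tr2, b, 8), oracle,
               tolerance = 1e-7)
})

test_that("event times invert the cumulative hazard", {
  wb <- baseline_hazard_spec("weibull", 0.1, 1.4)
  tr <- trajectory_spec(3.2)
  # alpha = 0: closed-form inversion of the Weibull cumulative hazard
  expect_equal(draw_event_time(wb, 0, tr, u = exp(-0.1)), 1)
  # constant marker, any alpha: matches the closed form to 1e-6
  set.seed(3)
  u <- runif(1000, 0.01, 0.99)
  closed <- (-log(u) * exp(-0.3 * 3.2) / 0.1)^(1 / 1.4)
  got <- vapply(u, function(ui) draw_event_time(wb, 0.3, tr, u = ui),
                numeric(1))
  expect_lt(max(abs(got - closed)), 1e-6)
  # vectorised solver agrees with the scalar root finder for sloped markers
  tr2 <- trajectory_spec(3.2, -0.07)
  set.seed(4)
  b <- cbind(rnorm(200, 0, 1.2), rnorm(200, 0, 0.2))
  u <- runif(200)
  tv <- jmsim:::solve_event_times(wb, 0.3, tr2, jmsim:::pad_effects(b), u)
  ts <- vapply(1:200, function(i) draw_event_time(wb, 0.3, tr2, b[i, ],
                                                  u = u[i]), numeric(1))
  fin <- is.finite(ts) & is.finite(tv)
  expect_true(all(is.finite(ts) == is.finite(tv)))
  expect_lt(max(abs(tv[fin] - ts[fin])), 5e-5)
})

test_that("with alpha = 0 the marginal event-time law is the baseline law", {
  # Kolmogorov-Smirnov distance against the closed-form Weibull survival
  sp <- scenario_preset(2, n = 1e5, alpha = 0)
  set.seed(12)
  b <- draw_random_effects(sp$random_effects, sp$n)
  u <- runif(sp$n)
  tt <- jmsim:::solve_event_times(sp$hazard, 0, sp$trajectory,
                                  jmsim:::pad_effects(b), u)
  ks <- suppressWarnings(ks.test(tt, function(q) 1 - exp(-0.1 * q^1.4)))
  expect_lt(unname(ks$statistic), 0.01)
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated cohorts obey the censoring and truncation contract", {
  sp <- scenario_preset(2, n = 500, sigma_eps = 0.3, seed = 77)
  co <- simulate_cohort(sp)
  surv <- co$survival; lat <- co$latent
  expect_equal(surv$time, pmin(lat$t_star, lat$censor, 14))
  expect_identical(surv$status,
                   as.integer(lat$t_star <= pmin(lat$censor, 14)))
  # retained measurements never exceed the observed time
  tmax <- tapply(co$longitudinal$time, co$longitudinal$id, max)
  expect_true(all(tmax <= surv$time[match(names(tmax), surv$id)] + 1e-12))
  # every subject keeps the baseline visit
  expect_setequal(co$longitudinal$id[co$longitudinal$time == 0], surv$id)
  # weekly schedule: at most 15 visits; uncensored-at-14 subjects have 15
  nvisit <- table(co$longitudinal$id)
  expect_lte(max(nvisit), 15)
  full <- surv$id[surv$time == 14]
  if (length(full)) expect_true(all(nvisit[as.character(full)] == 15))
  expect_length(sp$schedule, 15)
  expect_length(scenario_preset(2, schedule = "four_weekly")$schedule, 57)
})

test_that("identical seed and spec reproduce the cohort bit for bit", {
  sp <- scenario_preset(9, n = 120, sigma_eps = 0.5)
  a <- simulate_cohort(sp, seed = 5)
  b <- simulate_cohort(sp, seed = 5)
  expect_identical(a$longitudinal, b$longitudinal)
  expect_identical(a$survival, b$survival)
  expect_identical(a$latent, b$latent)
})

test_that("mean observed trajectory tracks the fixed effects", {
  sp <- scenario_preset(2, n = 1e4, sigma_eps = 0.3, seed = 88)
  co <- simulate_cohort(sp)
  base <- co$longitudinal[co$longitudinal$time == 0, ]
  # at t = 0 no survivorship selection has occurred yet
  se0 <- sd(base$y) / sqrt(nrow(base))
  expect_lt(abs(mean(base$y) - 3.2), 3 * se0)
})

test_that("scenario presets reproduce the protocol table", {
  s2 <- scenario_preset(2)
  expect_equal(s2$trajectory$beta1, -0.07)
  expect_equal(s2$random_effects$variances, c(1.44, 0.04))
  expect_equal(s2$hazard$family, "weibull")
  expect_equal(c(s2$hazard$lambda, s2$hazard$rho), c(0.1, 1.4))
  expect_equal(c(s2$n, s2$censor_upper, s2$admin_time), c(300, 14, 14))
  s8 <- scenario_preset(8)
  expect_equal(c(s8$trajectory$beta1, s8$trajectory$beta2), c(-0.16, 0.01))
  expect_equal(s8$random_effects$variances, c(1.44, 0.6, 0.09))
  s9 <- scenario_preset(9)
  expect_equal(s9$hazard$family, "nonmonotonic")
  expect_equal(c(s9$hazard$nu, s9$hazard$kappa, s9$hazard$c), c(1, 2, 10))
  expect_error(scenario_preset(0), "1..9")
  expect_error(scenario_preset(10), "1..9")
})

test_that("cohort CSVs round-trip losslessly", {
  co <- simulate_cohort(scenario_preset(2, n = 30), seed = 31)
  dir <- withr::local_tempdir()
  paths <- write_cohort_csv(co, dir, w_true = TRUE)
  long <- read.csv(paths["longitudinal"])
  expect_equal(long$y, co$longitudinal$y)
  surv <- read.csv(paths["survival"])
  expect_equal(surv$time, co$survival$time)
  expect_identical(surv$status, co$survival$status)
})
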