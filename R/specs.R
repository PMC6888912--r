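#' Fixed-effect trajectory specification
#'
#' Describes the population-mean biomarker trajectory
#' \eqn{\beta_0 + \beta_1 t + \beta_2 t^2} (marker units; time in weeks).
#'
#' @param beta0 Intercept, the mean marker value at `t = 0` (marker units).
#' @param beta1 Linear slope (units/week).
#' @param beta2 Quadratic coefficient (units/week^2).
#' @return An object of class `trajectory_spec`.
#' @examples
#' trajectory_spec(3.2, -0.07)
#' @export
trajectory_spec <- function(beta0, beta1 = 0, beta2 = 0) {
  stopifnot(is.numeric(beta0), is.numeric(beta1), is.numeric(beta2),
            length(beta0) == 1L, length(beta1) == 1L, length(beta2) == 1L,
            is.finite(beta0), is.finite(beta1), is.finite(beta2))
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2),
            class = "trajectory_spec")
}

#' Random-effects specification
#'
#' Distribution of the subject-level deviations \eqn{b_i = (b_{i0}, b_{i1},
#' b_{i2})} entering the trajectory. The `normal` family supports up to three
#' independent components with variances `variances` (a diagonal
#' between-subject covariance). The non-normal families (`bimodal`,
#' `chisquare`, `gamma`) describe the random intercept only
#' (`dimension = 1`); their shape parameters are fixed so that the
#' chi-square and gamma intercept variances match `variances[1]`, while the
#' bimodal mixture keeps its quoted component parameters.
#'
#' When `center_to_zero` is `TRUE` (default) the analytic mean of a
#' non-normal law is subtracted so the drawn effects have mean zero and the
#' population trajectory stays at `beta0 + beta1 t + beta2 t^2`.
#'
#' @param family One of `"normal"`, `"bimodal"`, `"chisquare"`, `"gamma"`.
#' @param variances Numeric vector (length = `dimension`) of variances for
#'   the normal family; for the other families only the first element is
#'   used as bookkeeping (see Details).
#' @param dimension Number of random effects (1 to 3); must be 1 for
#'   non-normal families.
#' @param center_to_zero Subtract the analytic mean of non-normal laws.
#' @param bimodal Mixture parameters for the bimodal family:
#'   `p * N(mean1, var) + (1 - p) * N(mean2, var)`.
#' @param chisq_df Degrees of freedom of the chi-square intercept law.
#' @param gamma_shape,gamma_scale Gamma intercept law parameters.
#' @return An object of class `random_effects_spec`.
#' @export
random_effects_spec <- function(family = c("normal", "bimodal", "chisquare", "gamma"),
                                variances = c(1.44, 0, 0),
                                dimension = length(variances),
                                center_to_zero = TRUE,
                                bimodal = list(p = 0.65, mean1 = 8, mean2 = 15, var = 1.44),
                                chisq_df = 0.72,
                                gamma_shape = 0.5,
                                gamma_scale = 1.7) {
  family <- match.arg(family)
  stopifnot(dimension >= 1L, dimension <= 3L)
  variances <- as.numeric(variances)
  if (length(variances) < dimension) {
    variances <- c(variances, rep(0, dimension - length(variances)))
  }
  variances <- variances[seq_len(dimension)]
  if (any(variances < 0)) stop("random-effect variances must be >= 0")
  if (family != "normal" && dimension > 1L) {
    stop("non-normal random-effect families are random-intercept only (dimension 1)")
  }
  structure(list(family = family, variances = variances,
                 dimension = as.integer(dimension),
                 center_to_zero = isTRUE(center_to_zero),
                 bimodal = bimodal, chisq_df = chisq_df,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale),
            class = "random_effects_spec")
}

#' Analytic mean and variance of a random-effects law
#'
#' Closed-form first and second moments of the random intercept under each
#' supported family, before any centering. Used for centering and as the
#' oracle in moment-matching tests.
#'
#' @param spec A [random_effects_spec()].
#' @return A list with elements `mean` and `variance` (per component).
#' @export
random_effects_moments <- function(spec) {
  stopifnot(inherits(spec, "random_effects_spec"))
  switch(spec$family,
    normal = list(mean = rep(0, spec$dimension), variance = spec$variances),
    chisquare = list(mean = spec$chisq_df, variance = 2 * spec$chisq_df),
    gamma = list(mean = spec$gamma_shape * spec$gamma_scale,
                 variance = spec$gamma_shape * spec$gamma_scale^2),
    bimodal = {
      b <- spec$bimodal
      m <- b$p * b$mean1 + (1 - b$p) * b$mean2
      v <- b$var + b$p * (1 - b$p) * (b$mean1 - b$mean2)^2
      list(mean = m, variance = v)
    })
}

#' Baseline hazard specification
#'
#' @param family `"weibull"` (\eqn{h_0(t) = \lambda \rho t^{\rho - 1}}),
#'   `"nonmonotonic"` (\eqn{h_0(t) = \nu \kappa t^{\kappa - 1} / (c + t^\kappa)})
#'   or `"constant"`.
#' @param lambda,rho Weibull scale and shape (both > 0).
#' @param nu,kappa,c Non-monotonic hazard parameters (all > 0); for
#'   `kappa > 1` the hazard starts at 0, rises and then decays.
#' @param rate Constant hazard rate (> 0).
#' @return An object of class `baseline_hazard_spec`.
#' @export
baseline_hazard_spec <- function(family = c("weibull", "nonmonotonic", "constant"),
                                 lambda = 0.1, rho = 1.4,
                                 nu = 1, kappa = 2, c = 10,
                                 rate = 0.1) {
  family <- match.arg(family)
  if (family == "weibull" && (lambda <= 0 || rho <= 0)) {
    stop("weibull baseline requires lambda > 0 and rho > 0")
  }
  if (family == "nonmonotonic" && (nu <= 0 || kappa <= 0 || c <= 0)) {
    stop("nonmonotonic baseline requires nu, kappa, c > 0")
  }
  if (family == "constant" && rate <= 0) stop("constant baseline requires rate > 0")
  structure(list(family = family, lambda = lambda, rho = rho,
                 nu = nu, kappa = kappa, c = c, rate = rate),
            class = "baseline_hazard_spec")
}

#' Full data-generating configuration for one simulation scenario
#'
#' Bundles everything needed to simulate one cohort: the mean trajectory,
#' the random-effects law, the measurement-error SD, the baseline hazard,
#' the association parameter linking the true marker value to the hazard,
#' the visit schedule, and the censoring mechanism (uniform censoring on
#' `(0, censor_upper)` combined with administrative end of follow-up at
#' `admin_time` weeks).
#'
#' @param id Integer scenario label (free-form; presets use 1-9).
#' @param n Cohort size.
#' @param trajectory A [trajectory_spec()].
#' @param random_effects A [random_effects_spec()].
#' @param sigma_eps Measurement-error SD (>= 0, marker units).
#' @param hazard A [baseline_hazard_spec()].
#' @param alpha Association parameter: log hazard ratio per marker unit.
#' @param schedule Ordered measurement times in weeks; must start at 0,
#'   be strictly increasing and end at or before `admin_time`.
#' @param censor_upper Upper bound of the uniform censoring time (weeks).
#' @param admin_time Administrative end of follow-up (weeks).
#' @param seed Optional integer seed stored with the spec.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(id = 0L, n = 300L,
                          trajectory = trajectory_spec(3.2, -0.07),
                          random_effects = random_effects_spec("normal", c(1.44, 0.04)),
                          sigma_eps = 0.3,
                          hazard = baseline_hazard_spec("weibull"),
                          alpha = 0.3,
                          schedule = 0:14,
                          censor_upper = 14,
                          admin_time = 14,
                          seed = NULL) {
  stopifnot(inherits(trajectory, "trajectory_spec"),
            inherits(random_effects, "random_effects_spec"),
            inherits(hazard, "baseline_hazard_spec"),
            is.numeric(sigma_eps), length(sigma_eps) == 1L,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            n >= 1)
  if (sigma_eps < 0) stop("sigma_eps must be >= 0")
  schedule <- as.numeric(schedule)
  if (length(schedule) < 1L || schedule[1] != 0) {
    stop("schedule must start at t = 0 (baseline measurement)")
  }
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  if (schedule[length(schedule)] > admin_time) {
    stop("schedule must end at or before admin_time")
  }
  if (censor_upper <= 0 || admin_time <= 0) {
    stop("censor_upper and admin_time must be positive")
  }
  structure(list(id = as.integer(id), n = as.integer(n),
                 trajectory = trajectory, random_effects = random_effects,
                 sigma_eps = sigma_eps, hazard = hazard, alpha = alpha,
                 schedule = schedule, censor_upper = censor_upper,
                 admin_time = admin_time, seed = seed),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  tr <- x$trajectory
  cat("Scenario", x$id, "- n =", x$n, "\n")
  cat(sprintf("  trajectory: %.4g + %.4g t + %.4g t^2\n", tr$beta0, tr$beta1, tr$beta2))
  cat(sprintf("  random effects: %s, variances (%s)\n", x$random_effects$family,
              paste(signif(x$random_effects$variances, 4), collapse = ", ")))
  cat(sprintf("  sigma_eps: %.3g   alpha: %.3g\n", x$sigma_eps, x$alpha))
  cat(sprintf("  baseline hazard: %s\n", x$hazard$family))
  cat(sprintf("  schedule: %d visits in [0, %g]; censoring U(0, %g), admin %g\n",
              length(x$schedule), max(x$schedule), x$censor_upper, x$admin_time))
  invisible(x)
}
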