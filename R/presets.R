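#' Scenario presets for the simulation protocol
#'
#' Returns the data-generating configuration of one of the nine study
#' scenarios. All presets share the Weibull(0.1, 1.4) baseline hazard
#' except scenario 9 (non-monotonic \eqn{\nu\kappa t^{\kappa-1}/(c +
#' t^\kappa)} with \eqn{\nu = 1, \kappa = 2, c = 10}), a weekly visit
#' schedule over 14 weeks, uniform censoring on (0, 14) and administrative
#' censoring at week 14.
#'
#' \describe{
#'   \item{1}{Constant marker `beta = (3.2, 0, 0)`, normal random intercept
#'     (variance 1.44).}
#'   \item{2}{Linearly decreasing marker `beta = (3.2, -0.07, 0)`, normal
#'     random intercept + slope, variances (1.44, 0.04).}
#'   \item{3-6}{Random-intercept-only versions of scenario 2 with the
#'     intercept drawn from a bimodal normal mixture
#'     (`0.65 N(8, 1.44) + 0.35 N(15, 1.44)`, centered), a chi-square (df
#'     0.72), a gamma (shape 0.5, scale 1.7) and a normal law.}
#'   \item{7}{Slightly quadratic marker `beta = (3.2, -0.07, 0.004)`,
#'     3-dimensional normal effects with variances (1.44, 0.6, 0.09).}
#'   \item{8}{Grossly quadratic marker `beta = (3.2, -0.16, 0.01)`, same
#'     random-effects structure as scenario 7.}
#'   \item{9}{As scenario 2 but with the non-monotonic baseline hazard.}
#' }
#'
#' @param id Scenario number, 1 to 9.
#' @param n Cohort size (default 300).
#' @param alpha Association parameter (default 0.3).
#' @param sigma_eps Measurement-error SD (default 0.3).
#' @param schedule `"weekly"` (t = 0, 1, ..., 14) or `"four_weekly"`
#'   (t = 0, 0.25, ..., 14), or a numeric vector of visit times.
#' @param seed Optional seed stored in the spec.
#' @return A [scenario_spec()].
#' @export
scenario_preset <- function(id, n = 300, alpha = 0.3, sigma_eps = 0.3,
                            schedule = "weekly", seed = NULL) {
  if (length(id) != 1L || !id %in% 1:9) {
    stop("unknown scenario id: ", deparse(substitute(id)),
         " = ", paste(id, collapse = ","), " (must be 1..9)")
  }
  if (is.character(schedule)) {
    schedule <- switch(match.arg(schedule, c("weekly", "four_weekly")),
                       weekly = seq(0, 14, by = 1),
                       four_weekly = seq(0, 14, by = 0.25))
  }
  traj <- switch(as.character(id),
    "1" = trajectory_spec(3.2, 0, 0),
    "7" = trajectory_spec(3.2, -0.07, 0.004),
    "8" = trajectory_spec(3.2, -0.16, 0.01),
    trajectory_spec(3.2, -0.07, 0))
  re <- switch(as.character(id),
    "1" = random_effects_spec("normal", 1.44),
    "2" = random_effects_spec("normal", c(1.44, 0.04)),
    "3" = random_effects_spec("bimodal", 1.44),
    "4" = random_effects_spec("chisquare", 1.44),
    "5" = random_effects_spec("gamma", 1.44),
    "6" = random_effects_spec("normal", 1.44),
    "7" = random_effects_spec("normal", c(1.44, 0.6, 0.09)),
    "8" = random_effects_spec("normal", c(1.44, 0.6, 0.09)),
    "9" = random_effects_spec("normal", c(1.44, 0.04)))
  haz <- if (id == 9) {
    baseline_hazard_spec("nonmonotonic", nu = 1, kappa = 2, c = 10)
  } else {
    baseline_hazard_spec("weibull", lambda = 0.1, rho = 1.4)
  }
  scenario_spec(id = id, n = n, trajectory = traj, random_effects = re,
                sigma_eps = sigma_eps, hazard = haz, alpha = alpha,
                schedule = schedule, censor_upper = 14, admin_time = 14,
                seed = seed)
}
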