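#' Simulate one cohort under a scenario specification
#'
#' Generates a complete synthetic cohort: random effects are drawn, true
#' trajectories evaluated on the visit schedule, latent event times
#' obtained by inverting the subject-specific cumulative hazard, censoring
#' times drawn as `C ~ Uniform(0, censor_upper)`, and the observed time set
#' to `T = min(T*, C, admin_time)` with event indicator `delta = 1` iff the
#' latent event time is the minimum. Observed marker values are the true
#' values plus Gaussian measurement error; measurements taken after `T` are
#' discarded (the baseline visit at `t = 0` is always retained).
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed (defaults to `spec$seed`); `NULL` leaves the
#'   RNG state untouched.
#' @return An object of class `cohort_sim`: a list with
#'   \describe{
#'     \item{longitudinal}{data.frame `id`, `time`, `y`, `w_true` (retained visits only).}
#'     \item{survival}{data.frame `id`, `time`, `status` (1 = event, 0 = censored).}
#'     \item{latent}{data.frame `id`, `b0`, `b1`, `b2`, `t_star`, `censor` with the
#'       latent per-subject quantities.}
#'     \item{spec, seed}{the generating configuration.}
#'   }
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  times <- spec$schedule
  m <- length(times)

  b <- draw_random_effects(spec$random_effects, n)
  bp <- pad_effects(b)
  W <- trajectory_matrix(spec$trajectory, bp, times)

  u <- stats::runif(n)
  t_star <- solve_event_times(spec$hazard, spec$alpha, spec$trajectory, bp, u)
  cens <- stats::runif(n, 0, spec$censor_upper)
  t_obs <- pmin(t_star, cens, spec$admin_time)
  delta <- as.integer(t_star <= pmin(cens, spec$admin_time))

  Y <- W
  if (spec$sigma_eps > 0) {
    Y <- W + matrix(stats::rnorm(n * m, sd = spec$sigma_eps), n, m)
  }

  keep <- outer(t_obs, times, `>=`)        # visit retained iff time <= T
  keep[, 1] <- TRUE                        # baseline always kept (T > 0 a.s.)
  idx <- which(t(keep))                    # row-major over subjects
  id_long <- rep(seq_len(n), times = rowSums(keep))
  time_long <- rep(times, n)[idx]
  longitudinal <- data.frame(id = id_long, time = time_long,
                             y = t(Y)[idx], w_true = t(W)[idx])

  structure(list(
    longitudinal = longitudinal,
    survival = data.frame(id = seq_len(n), time = t_obs, status = delta),
    latent = data.frame(id = seq_len(n), b0 = bp[, 1], b1 = bp[, 2],
                        b2 = bp[, 3], t_star = t_star, censor = cens),
    spec = spec, seed = seed), class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  n <- nrow(x$survival)
  cat(sprintf("Simulated cohort: %d subjects, %d measurements, %.1f%% events\n",
              n, nrow(x$longitudinal), 100 * mean(x$survival$status)))
  invisible(x)
}

#' Restrict a cohort to a coarser visit schedule
#'
#' Keeps only the longitudinal measurements taken at times in `schedule`
#' (within a small numeric tolerance). Used to obtain the weekly view of a
#' cohort generated on a denser schedule, so that both views share the same
#' subjects, random effects, survival times and noise draws at common
#' visits.
#'
#' @param cohort A `cohort_sim`.
#' @param schedule Times to retain (default: integer weeks).
#' @return A `cohort_sim` with the thinned longitudinal table.
#' @export
thin_schedule <- function(cohort, schedule = 0:14) {
  stopifnot(inherits(cohort, "cohort_sim"))
  keep <- vapply(cohort$longitudinal$time,
                 function(t) any(abs(t - schedule) < 1e-9), logical(1))
  out <- cohort
  out$longitudinal <- cohort$longitudinal[keep, , drop = FALSE]
  row.names(out$longitudinal) <- NULL
  out$spec$schedule <- schedule[schedule <= max(cohort$spec$schedule)]
  out
}

#' Write cohort tables to CSV
#'
#' Writes the longitudinal table (`id`, `time`, `y`, and optionally
#' `w_true`) and the survival table (`id`, `time`, `status`) as plain CSV.
#'
#' @param cohort A `cohort_sim`.
#' @param dir Output directory (created if needed).
#' @param w_true Include the latent true marker column.
#' @return Invisibly, the two file paths.
#' @export
write_cohort_csv <- function(cohort, dir, w_true = FALSE) {
  stopifnot(inherits(cohort, "cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- cohort$longitudinal
  if (!w_true) long$w_true <- NULL
  f1 <- file.path(dir, "longitudinal.csv")
  f2 <- file.path(dir, "survival.csv")
  utils::write.csv(format_numeric_df(long), f1, row.names = FALSE, quote = FALSE)
  utils::write.csv(format_numeric_df(cohort$survival), f2, row.names = FALSE,
                   quote = FALSE)
  invisible(c(longitudinal = f1, survival = f2))
}

# serialize doubles at full precision so CSV round-trips are lossless
format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}
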