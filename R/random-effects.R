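#' Draw subject-level random effects
#'
#' Samples `n` random-effect vectors under the law described by `spec`.
#' The normal family draws independent components with the requested
#' variances. Non-normal families (random intercept only) draw from the
#' bimodal normal mixture, a chi-square, or a gamma law; when
#' `spec$center_to_zero` is set the analytic mean of the law is subtracted
#' so the effects have mean zero while keeping their variance.
#'
#' @param spec A [random_effects_spec()].
#' @param n Number of subjects (>= 1).
#' @return An `n x dimension` numeric matrix.
#' @export
draw_random_effects <- function(spec, n) {
  stopifnot(inherits(spec, "random_effects_spec"), n >= 1)
  n <- as.integer(n)
  d <- spec$dimension
  if (spec$family == "normal") {
    sds <- sqrt(spec$variances)
    b <- matrix(stats::rnorm(n * d), n, d)
    return(sweep(b, 2L, sds, `*`))
  }
  # random-intercept-only families
  b0 <- switch(spec$family,
    chisquare = stats::rchisq(n, df = spec$chisq_df),
    gamma = stats::rgamma(n, shape = spec$gamma_shape, scale = spec$gamma_scale),
    bimodal = {
      bm <- spec$bimodal
      comp <- stats::runif(n) < bm$p
      mu <- ifelse(comp, bm$mean1, bm$mean2)
      stats::rnorm(n, mean = mu, sd = sqrt(bm$var))
    })
  if (spec$center_to_zero) {
    b0 <- b0 - random_effects_moments(spec)$mean
  }
  matrix(b0, n, 1L)
}

# pad an effects matrix (or vector) with zero columns up to 3 components
pad_effects <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (ncol(b) < 3L) b <- cbind(b, matrix(0, nrow(b), 3L - ncol(b)))
  b
}

#' Evaluate a subject's true trajectory
#'
#' Computes \eqn{w(t) = (\beta_0 + b_0) + (\beta_1 + b_1) t + (\beta_2 +
#' b_2) t^2}. `b` is padded with zeros to length 3, so a random-intercept
#' subject can pass a length-1 vector.
#'
#' @param traj A [trajectory_spec()].
#' @param b Random-effect vector of length 1 to 3 (default all zero).
#' @param times Evaluation times (finite numeric vector).
#' @return Numeric vector of true marker values, one per time.
#' @export
true_trajectory <- function(traj, b = c(0, 0, 0), times) {
  stopifnot(inherits(traj, "trajectory_spec"), all(is.finite(times)))
  b <- as.numeric(b)
  if (length(b) > 3L) stop("b has more than 3 components")
  b <- c(b, rep(0, 3L - length(b)))
  (traj$beta0 + b[1]) + (traj$beta1 + b[2]) * times + (traj$beta2 + b[3]) * times^2
}

# n x length(times) matrix of true trajectories, rows = subjects
trajectory_matrix <- function(traj, b, times) {
  b <- pad_effects(b)
  beta <- c(traj$beta0, traj$beta1, traj$beta2)
  Tm <- rbind(1, times, times^2)
  sweep(b, 2L, beta, `+`) %*% Tm
}

#' Add Gaussian measurement error to true marker values
#'
#' @param w Vector of true marker values.
#' @param sigma_eps Measurement-error SD (>= 0). With `sigma_eps = 0` the
#'   returned values equal `w` exactly.
#' @return Vector of observed values `y = w + e`, `e ~ N(0, sigma_eps^2)`.
#' @export
observe_marker <- function(w, sigma_eps) {
  stopifnot(all(is.finite(w)), is.numeric(sigma_eps), length(sigma_eps) == 1L)
  if (sigma_eps < 0) stop("sigma_eps must be >= 0")
  if (sigma_eps == 0) return(w)
  w + stats::rnorm(length(w), sd = sigma_eps)
}
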