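#' Polynomial time bases for the longitudinal submodel
#'
#' @param times Numeric vector of times.
#' @param form `"constant"` (intercept only), `"linear"` or `"quadratic"`.
#' @return Design matrix with columns drawn from `{1, t, t^2}`.
#' @export
time_basis <- function(times, form = c("linear", "constant", "quadratic")) {
  form <- match.arg(form)
  switch(form,
    constant = cbind(`(Intercept)` = rep(1, length(times))),
    linear = cbind(`(Intercept)` = 1, time = times),
    quadratic = cbind(`(Intercept)` = 1, time = times, time2 = times^2))
}

basis_dim <- function(form) {
  c(constant = 1L, intercept = 1L, linear = 2L, quadratic = 3L)[[form]]
}

#' Fit the linear mixed longitudinal submodel
#'
#' Restricted maximum likelihood fit of
#' \eqn{y_{ij} = \beta^T f(t_{ij}) + b_i^T g(t_{ij}) + e_{ij}} with
#' `f`, `g` polynomial bases in time and normally distributed random
#' effects. The random basis must be a subset of the fixed basis. The fit
#' is delegated to `lme4::lmer`; the function returns the estimates,
#' the empirical-Bayes random-effect modes, and the conditional
#' (posterior) covariances used to center adaptive quadrature.
#'
#' @param longitudinal data.frame with columns `id`, `time`, `y`.
#' @param fixed `"constant"`, `"linear"` or `"quadratic"`.
#' @param random `"intercept"`, `"linear"` or `"quadratic"` (the random
#'   basis uses the leading columns of the fixed basis).
#' @return An object of class `lmm_fit`: list with `beta`, `Sigma` (d x d),
#'   `sigma` (residual SD), `ranef` (n x d empirical-Bayes modes, rows
#'   named by subject id), `cond_var` (d x d x n), `loglik` (REML
#'   criterion), `singular` (variance on the boundary) and `converged`.
#' @export
fit_lmm <- function(longitudinal, fixed = "linear", random = "linear") {
  stopifnot(all(c("id", "time", "y") %in% names(longitudinal)))
  pf <- basis_dim(fixed)
  d <- basis_dim(random)
  if (d > pf) stop("the random basis must be a subset of the fixed basis")
  df <- data.frame(id = factor(longitudinal$id), time = longitudinal$time,
                   y = longitudinal$y)
  fe <- switch(pf, "1", "time", "time + I(time^2)")
  re <- switch(d, "1", "1 + time", "1 + time + I(time^2)")
  fml <- stats::as.formula(paste0("y ~ ", fe, " + (", re, " | id)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lme4::lmer(fml, data = df, REML = TRUE,
                                                 control = ctrl))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(beta = rep(NA_real_, pf), Sigma = matrix(NA, d, d),
                          sigma = NA_real_, ranef = NULL, cond_var = NULL,
                          loglik = NA_real_, fixed = fixed, random = random,
                          singular = TRUE, converged = FALSE),
                     class = "lmm_fit"))
  }
  beta <- unname(lme4::fixef(fit))
  vc <- lme4::VarCorr(fit)
  Sigma <- matrix(as.numeric(vc$id), d, d)
  sigma <- stats::sigma(fit)
  re_obj <- lme4::ranef(fit, condVar = TRUE)$id
  bhat <- as.matrix(re_obj)
  pv <- attr(re_obj, "postVar")         # d x d x n
  structure(list(beta = beta, Sigma = Sigma, sigma = sigma,
                 ranef = bhat, cond_var = pv,
                 loglik = as.numeric(stats::logLik(fit)),
                 fixed = fixed, random = random,
                 singular = lme4::isSingular(fit), converged = TRUE),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model fit (", x$fixed, "fixed /", x$random, "random )\n")
  cat("  beta:", paste(signif(x$beta, 5), collapse = ", "), "\n")
  cat("  sigma_eps:", signif(x$sigma, 5), "\n")
  cat("  random-effect variances:",
      paste(signif(diag(x$Sigma), 5), collapse = ", "), "\n")
  invisible(x)
}

#' Empirical-Bayes predicted trajectory for one subject
#'
#' Evaluates \eqn{\hat w_i(t) = \hat\beta^T f(t) + \hat b_i^T g(t)} at the
#' requested times, using the subject's empirical-Bayes random-effect mode.
#'
#' @param lmm An `lmm_fit`.
#' @param id One subject identifier present in the fitted data.
#' @param times Evaluation times.
#' @return Numeric vector of fitted marker values.
#' @export
predict_trajectory <- function(lmm, id, times) {
  stopifnot(inherits(lmm, "lmm_fit"), lmm$converged)
  F <- time_basis(times, lmm$fixed)
  G <- F[, seq_len(ncol(lmm$ranef)), drop = FALSE]
  i <- match(as.character(id), rownames(lmm$ranef))
  if (is.na(i)) stop("unknown subject id: ", id)
  drop(F %*% lmm$beta + G %*% as.numeric(lmm$ranef[i, ]))
}
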