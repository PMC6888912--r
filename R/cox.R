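#' Expand a cohort into counting-process (start, stop] records
#'
#' Builds the last-observation-carried-forward expansion used by the
#' time-varying covariate Cox model: each subject's follow-up `(0, T]` is
#' cut at their measurement times, and each interval `(start, stop]`
#' carries the marker value observed at `start` (the most recent
#' measurement). The final interval ends at the observed time `T` and
#' carries the event flag.
#'
#' @param longitudinal data.frame with columns `id`, `time`, `y`; every
#'   subject must have a baseline measurement at `time = 0`.
#' @param survival data.frame with columns `id`, `time` (> 0) and `status`.
#' @return A data.frame of class `counting_process` with columns `id`,
#'   `start`, `stop`, `status`, `x`.
#' @export
expand_locf <- function(longitudinal, survival) {
  stopifnot(all(c("id", "time", "y") %in% names(longitudinal)),
            all(c("id", "time", "status") %in% names(survival)))
  if (any(survival$time <= 0)) stop("survival times must be positive")
  miss <- setdiff(survival$id, longitudinal$id)
  if (length(miss)) {
    stop("subjects in the survival table missing from the longitudinal table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  surv_t <- survival$time[match(longitudinal$id, survival$id)]
  keep <- longitudinal$time < surv_t          # a visit at exactly T never
  long <- longitudinal[keep, , drop = FALSE]  # covers any later risk time
  if (!all(survival$id %in% long$id)) {
    stop("every subject needs a baseline measurement at time 0")
  }
  o <- order(long$id, long$time)
  long <- long[o, , drop = FALSE]
  if (any(long$time[!duplicated(long$id)] != 0)) {
    stop("every subject needs a baseline measurement at time 0")
  }
  last <- !duplicated(long$id, fromLast = TRUE)
  stop_t <- c(long$time[-1], NA_real_)
  stop_t[last] <- survival$time[match(long$id[last], survival$id)]
  status <- integer(nrow(long))
  status[last] <- survival$status[match(long$id[last], survival$id)]
  out <- data.frame(id = long$id, start = long$time, stop = stop_t,
                    status = status, x = long$y)
  class(out) <- c("counting_process", "data.frame")
  out
}

#' Cox partial log-likelihood for a single covariate
#'
#' Evaluates the counting-process Cox partial log-likelihood at `alpha`,
#' with Efron handling of tied event times, together with its first two
#' derivatives.
#'
#' @param alpha Association parameter (log hazard ratio per covariate unit).
#' @param data A `counting_process` data.frame (see [expand_locf()]).
#' @return List with `loglik`, `gradient` and `hessian` (the hessian is
#'   minus the observed information; the likelihood is concave).
#' @export
cox_partial_loglik <- function(alpha, data) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            all(c("start", "stop", "status", "x") %in% names(data)))
  if (sum(data$status) == 0) stop("no events in the data")
  r <- cox_pl_cpp(alpha, data$start, data$stop, as.integer(data$status), data$x)
  list(loglik = r$loglik, gradient = r$score, hessian = -r$info)
}

#' Fit the Cox model by Newton-Raphson on the partial likelihood
#'
#' Maximises the single-covariate counting-process partial likelihood.
#' Convergence is declared when the relative log-likelihood change drops
#' below `1e-9` or the score below `1e-8` in absolute value. A monotone
#' likelihood (estimate drifting past `|alpha| > 20`) is reported through
#' the `converged` flag rather than an error.
#'
#' @param data A `counting_process` data.frame.
#' @param init Starting value for alpha.
#' @param max_iter Iteration cap.
#' @return An object of class `cox_fit`: list with `alpha`, `se`, `loglik`,
#'   `iterations`, `converged`.
#' @export
fit_cox <- function(data, init = 0, max_iter = 50L) {
  if (sum(data$status) == 0) stop("no events in the data")
  alpha <- init
  fit <- cox_partial_loglik(alpha, data)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    info <- -fit$hessian
    if (!is.finite(info) || info <= 0) break
    step <- fit$gradient / info
    new_alpha <- alpha + step
    new_fit <- cox_partial_loglik(new_alpha, data)
    halvings <- 0L
    while (new_fit$loglik < fit$loglik && halvings < 20L) {
      step <- step / 2
      new_alpha <- alpha + step
      new_fit <- cox_partial_loglik(new_alpha, data)
      halvings <- halvings + 1L
    }
    rel <- abs(new_fit$loglik - fit$loglik) / (abs(fit$loglik) + 1e-12)
    alpha <- new_alpha
    fit <- new_fit
    if (abs(alpha) > 20) break
    if (rel < 1e-9 || abs(fit$gradient) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  info <- -fit$hessian
  se <- if (converged && info > 0) 1 / sqrt(info) else NA_real_
  structure(list(alpha = alpha, se = se, loglik = fit$loglik,
                 iterations = it, converged = converged && abs(alpha) <= 20),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox partial-likelihood fit\n")
  cat(sprintf("  alpha = %.4f (se %.4f), HR = %.3f\n", x$alpha, x$se,
              exp(x$alpha)))
  cat(sprintf("  loglik = %.4f, %d iterations, converged: %s\n",
              x$loglik, x$iterations, x$converged))
  invisible(x)
}

#' Baseline-measurement Cox model
#'
#' Fits the ordinary Cox model using only each subject's baseline marker
#' value `y(0)` as a fixed covariate — a single `(0, T]` record per
#' subject.
#'
#' @inheritParams expand_locf
#' @return A `cox_fit`.
#' @export
fit_cox_baseline <- function(longitudinal, survival) {
  base <- longitudinal[longitudinal$time == 0, , drop = FALSE]
  fit_cox(expand_locf(base, survival))
}

#' Two-stage estimator: mixed model then Cox
#'
#' Stage 1 fits the linear mixed model ([fit_lmm()]) to the observed
#' longitudinal marker. Stage 2 fits the time-varying covariate Cox model
#' with the covariate replaced by each subject's empirical-Bayes fitted
#' trajectory \eqn{\hat w_i(t)}, refreshed at every distinct event time
#' (which is exact for the partial likelihood, evaluated only at event
#' times).
#'
#' @inheritParams expand_locf
#' @param fixed,random Longitudinal model forms, as in [fit_lmm()].
#' @return A `cox_fit` with the stage-1 fit attached as attribute `lmm`.
#' @export
two_stage_fit <- function(longitudinal, survival, fixed = "linear",
                          random = "linear") {
  lmm <- fit_lmm(longitudinal, fixed = fixed, random = random)
  if (!lmm$converged) {
    out <- structure(list(alpha = NA_real_, se = NA_real_, loglik = NA_real_,
                          iterations = 0L, converged = FALSE),
                     class = "cox_fit")
    attr(out, "lmm") <- lmm
    return(out)
  }
  ev <- sort(unique(survival$time[survival$status == 1]))
  ids <- survival$id
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    Ti <- survival$time[k]
    cuts <- ev[ev < Ti]
    starts <- c(0, cuts)
    stops <- c(cuts, Ti)
    w <- predict_trajectory(lmm, ids[k], stops)
    rows[[k]] <- data.frame(id = ids[k], start = starts, stop = stops,
                            status = c(rep(0L, length(cuts)),
                                       survival$status[k]),
                            x = w)
  }
  cp <- do.call(rbind, rows)
  class(cp) <- c("counting_process", "data.frame")
  out <- fit_cox(cp)
  attr(out, "lmm") <- lmm
  out
}

#' Read/write counting-process CSV
#'
#' Lossless round-trip of the `(id, start, stop, status, x)` table.
#' @param data A `counting_process` data.frame.
#' @param path CSV file path.
#' @return `write_counting_process()`: the path, invisibly;
#'   `read_counting_process()`: the table.
#' @export
write_counting_process <- function(data, path) {
  utils::write.csv(format_numeric_df(as.data.frame(data)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counting_process
#' @export
read_counting_process <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("counting_process", "data.frame")
  out
}
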