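#' Summarise Monte-Carlo estimates of the association parameter
#'
#' Computes the study's summary metrics from a vector of replicate
#' estimates and their reported standard errors: mean estimate (Est),
#' empirical Monte-Carlo SE (ESE, sample SD of the estimates), asymptotic
#' SE (ASE, mean of the reported SEs), bias, percentage bias
#' (`100 * Bias / alpha_true`; reported as the raw bias when `alpha_true
#' = 0`), 95% Wald coverage probability and mean squared error.
#'
#' @param estimates Replicate estimates (length >= 2).
#' @param ses Replicate standard errors (same length).
#' @param alpha_true True association parameter.
#' @return A one-row data.frame with columns `Est`, `ESE`, `ASE`, `Bias`,
#'   `PctBias`, `CP`, `MSE`, `B_used`.
#' @export
summarize_metrics <- function(estimates, ses, alpha_true) {
  B <- length(estimates)
  if (B < 2) stop("need at least 2 estimates to summarise")
  stopifnot(length(ses) == B)
  est <- mean(estimates)
  ese <- stats::sd(estimates)
  bias <- est - alpha_true
  covered <- (estimates - 1.96 * ses <= alpha_true) &
             (alpha_true <= estimates + 1.96 * ses)
  data.frame(Est = est, ESE = ese, ASE = mean(ses), Bias = bias,
             PctBias = if (alpha_true != 0) 100 * bias / alpha_true else bias,
             CP = mean(covered),
             MSE = mean((estimates - alpha_true)^2),
             B_used = B)
}

#' Drop non-converged and outlying replicate estimates
#'
#' Removes non-converged fits, then flags outliers among the remaining
#' estimates: `|estimate| > 5` or more than 10 interquartile ranges from
#' the median. Both exclusion counts are returned.
#'
#' @param estimates,ses Aligned replicate vectors.
#' @param converged Logical vector of convergence flags.
#' @return List with `estimates`, `ses`, `kept` (indices into the input),
#'   `n_nonconverged`, `n_outliers_removed`.
#' @export
exclusion_filter <- function(estimates, ses, converged) {
  stopifnot(length(estimates) == length(ses),
            length(estimates) == length(converged))
  conv <- converged & is.finite(estimates) & is.finite(ses)
  idx <- which(conv)
  if (!length(idx)) stop("all replicates excluded (no converged fits)")
  e <- estimates[idx]
  iqr <- stats::IQR(e)
  out <- abs(e) > 5
  if (iqr > 0) out <- out | abs(e - stats::median(e)) > 10 * iqr
  keep <- idx[!out]
  if (!length(keep)) stop("all replicates excluded")
  list(estimates = estimates[keep], ses = ses[keep], kept = keep,
       n_nonconverged = sum(!conv),
       n_outliers_removed = sum(out))
}
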