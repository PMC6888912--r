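# Shared small fixtures, built once per test run.

# a moderate scenario-2 cohort reused across Cox / LMM / joint tests
s2_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- simulate_cohort(scenario_preset(2, n = 300, sigma_eps = 0.3),
                               seed = 20240901)
    }
    memo
  }
})

# tiny hand-checkable counting-process dataset: 3 subjects, time-fixed
# covariate (0, 1, 0), events at t = 1 and t = 2, censored at t = 3;
# the partial-likelihood MLE is log(sqrt(2))
toy_counting_process <- function() {
  cp <- data.frame(id = 1:3, start = 0, stop = c(1, 2, 3),
                   status = c(1L, 1L, 0L), x = c(0, 1, 0))
  class(cp) <- c("counting_process", "data.frame")
  cp
}

# Monte-Carlo oracle for the marginal joint likelihood of a small dataset:
# per subject, log mean over plain normal random-effect draws of
# exp(conditional loglik), vectorised over draws, Gauss-Legendre for the
# cumulative hazard (same rule as the model likelihood).
mc_marginal_loglik <- function(longitudinal, survival, params, hazard,
                               fixed = "linear", n_draws = 1e6, seed = 1,
                               gl_nodes = 15, chunk = 2e5) {
  set.seed(seed)
  Sigma <- as.matrix(params$Sigma)
  d <- nrow(Sigma)
  Lc <- t(chol(Sigma))
  total <- 0
  for (id in survival$id) {
    rows <- longitudinal$id == id
    y <- longitudinal$y[rows]; tt <- longitudinal$time[rows]
    Ti <- survival$time[survival$id == id]
    di <- survival$status[survival$id == id]
    X <- time_basis(tt, fixed)
    Z <- X[, seq_len(d), drop = FALSE]
    mu0 <- drop(X %*% params$beta)
    gl <- pracma::gaussLegendre(gl_nodes, 0, Ti)
    Fs <- time_basis(gl$x, fixed)
    Gs <- Fs[, seq_len(d), drop = FALSE]
    base_s <- drop(Fs %*% params$beta)
    h0s <- baseline_hazard(hazard, gl$x)
    fT <- time_basis(Ti, fixed)
    wT0 <- drop(fT %*% params$beta)
    gT <- fT[, seq_len(d), drop = FALSE]
    sum_exp <- 0
    n_done <- 0
    while (n_done < n_draws) {
      nc <- min(chunk, n_draws - n_done)
      B <- matrix(rnorm(nc * d), nc, d) %*% t(Lc)
      ll <- rep(-0.5 * length(y) * log(2 * pi * params$sigma_eps^2), nc)
      if (length(y)) {
        R <- matrix(y - mu0, nc, length(y), byrow = TRUE) - B %*% t(Z)
        ll <- ll - rowSums(R^2) / (2 * params$sigma_eps^2)
      }
      W <- matrix(base_s, nc, gl_nodes, byrow = TRUE) + B %*% t(Gs)
      H <- drop(exp(params$alpha * W) %*% (gl$w * h0s))
      ll <- ll - H
      if (di == 1) {
        ll <- ll + log(baseline_hazard(hazard, Ti)) +
          params$alpha * (wT0 + drop(B %*% t(gT)))
      }
      sum_exp <- sum_exp + sum(exp(ll))
      n_done <- n_done + nc
    }
    total <- total + log(sum_exp / n_draws)
  }
  total
}
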