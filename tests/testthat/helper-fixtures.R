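# Shared fixtures and independent oracles used across the suite.

# A small, fast cohort configuration for structural tests.
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_samples = 40L, n_genes = 60L, n_signal_genes = 10L,
         n_confounded_genes = 10L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Brute-force OLS via the normal equations (independent of the package's
# QR-based solver).
oracle_ols <- function(y, x1, x2) {
  X <- cbind(1, x1, x2)
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - 3L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(solve(xtx)))
  tstat <- beta[2L] / se[2L]
  list(beta = as.numeric(beta), se_ctc = unname(se[2L]),
       p = unname(2 * stats::pt(abs(tstat), df, lower.tail = FALSE)))
}

# Exact two-sided rank-sum p by enumeration of all group assignments
# (two-sided = twice the smaller tail, capped at 1 — the convention of the
# exact Wilcoxon distribution for continuous data).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  w_all <- apply(idx, 2L, function(ii) sum(r[ii])) - n1 * (n1 + 1) / 2
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns.
oracle_signrank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  lo <- mean(v_all <= v_obs)
  hi <- mean(v_all >= v_obs)
  min(1, 2 * min(lo, hi))
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins, summing probabilities no greater than the observed one
# (with the same relative tolerance R uses for ties in likelihood).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1L, ])
  n <- sum(tab[2L, ])
  k <- sum(tab[, 1L])
  x_obs <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Cox partial log-likelihood for a single binary covariate, Breslow ties.
oracle_cox_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1L)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
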