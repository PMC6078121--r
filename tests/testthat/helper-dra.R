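# Shared fixtures and independent oracles.  Oracles deliberately use
# naive per-patient / per-risk-set loops (or stats/survival fits) so they
# share no code path with the package's vectorized implementations.

fast_run <- function(root, ...) {
  dra_run(root, poll_interval = 0.01, timeout = 30, ...)
}

pooled_data <- function(cohort, site_col = FALSE) {
  parts <- lapply(seq_len(cohort$n_partners), function(k) {
    ds <- generate_partner_dataset(cohort, k)
    if (site_col) ds$site <- k
    ds
  })
  do.call(rbind, parts)
}

small_logistic_cohort <- function(seed = 42L, n = 150L) {
  cohort_spec("logistic", 3L, n,
              list(cov_normal("x1"), cov_bernoulli("x2", 0.4),
                   cov_uniform("x3", -1, 1)),
              true_beta = c(-0.5, 0.4, -0.3, 0.6), seed = seed)
}

small_cox_cohort <- function(seed = 42L, n = 150L) {
  cohort_spec("cox", 3L, n,
              list(cov_normal("x1"), cov_bernoulli("x2", 0.4)),
              true_beta = c(0.5, -0.3), censoring_rate = 0.5,
              site_effect_sd = 0.3, seed = seed)
}

# brute-force per-patient logistic score/information/loglik
logistic_oracle <- function(X, y, beta) {
  p <- ncol(X)
  g <- numeric(p); I <- matrix(0, p, p); ll <- 0
  for (i in seq_len(nrow(X))) {
    eta <- sum(X[i, ] * beta)
    pi <- 1 / (1 + exp(-eta))
    g <- g + X[i, ] * (y[i] - pi)
    I <- I + pi * (1 - pi) * tcrossprod(X[i, ])
    ll <- ll + y[i] * log(pi) + (1 - y[i]) * log(1 - pi)
  }
  list(gradient = g, information = I, loglik = ll)
}

# direct risk-set enumeration of the Breslow partial likelihood pieces
cox_oracle <- function(X, time, event, beta) {
  X <- as.matrix(X)
  p <- ncol(X)
  g <- numeric(p); I <- matrix(0, p, p); ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    R <- which(time >= t)
    D <- which(time == t & event == 1)
    XR <- X[R, , drop = FALSE]
    w <- exp(drop(XR %*% beta))
    S0 <- sum(w)
    S1 <- colSums(XR * w)
    S2 <- t(XR) %*% (XR * w)
    d <- length(D)
    ll <- ll + sum(drop(X[D, , drop = FALSE] %*% beta)) - d * log(S0)
    g <- g + colSums(X[D, , drop = FALSE]) - d * S1 / S0
    I <- I + d * (S2 / S0 - tcrossprod(S1 / S0))
  }
  list(gradient = g, information = I, loglik = ll)
}

# exact pooled AUC by the rank (Mann-Whitney) formula
rank_auc <- function(pred, y) {
  r <- rank(pred)
  nc <- sum(y == 1); nn <- sum(y == 0)
  (sum(r[y == 1]) - nc * (nc + 1) / 2) / (nc * nn)
}

# binned Hosmer-Lemeshow pieces computed directly on pooled data
pooled_binned_hl <- function(pred, y, edges) {
  bin <- findInterval(pred, edges, rightmost.closed = TRUE, all.inside = TRUE)
  f <- factor(bin, levels = seq_len(length(edges) - 1L))
  n_g <- as.numeric(table(f))
  O <- as.numeric(tapply(y, f, sum, default = 0))
  E <- as.numeric(tapply(pred, f, sum, default = 0))
  keep <- n_g > 0
  sum((O[keep] - E[keep])^2 / (E[keep] * (1 - E[keep] / n_g[keep])))
}
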