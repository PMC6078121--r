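#' Local score, information, and partial log-likelihood for Cox regression
#'
#' Each partner is treated as its own stratum: risk sets are formed only
#' from that partner's patients and never cross sites.  The resulting
#' statistics sum across partners to exactly the score, observed
#' information, and partial log-likelihood of a pooled Cox model
#' stratified by site, which is the pooled-equivalence target of the
#' distributed fit.  Tied event times use the Breslow approximation,
#' which keeps every contribution additive.
#'
#' For an event time t with d tied events, risk-set sums
#' `S0 = sum(exp(eta))`, `S1 = sum(x exp(eta))`, `S2 = sum(x x' exp(eta))`
#' over patients still at risk give contributions
#' `loglik += sum(eta_events) - d log S0`,
#' `score  += sum(x_events) - d S1/S0`,
#' `info   += d (S2/S0 - (S1/S0)(S1/S0)')`.
#' Censored patients tied with an event time are kept in that risk set.
#'
#' A partner with no events contributes zero to all three statistics.
#'
#' @param X n-by-p covariate matrix (no intercept).
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param beta Parameter vector of length p.
#' @param iteration,partner_id Protocol bookkeeping echoed in the payload.
#' @return A `dra_score_info` payload.
#' @export
cox_local_score_info <- function(X, time, event, beta,
                                 iteration = 1L, partner_id = NA_integer_) {
  X <- as.matrix(X)
  time <- as.numeric(time)
  event <- as.numeric(event)
  n <- nrow(X)
  p <- ncol(X)
  if (length(time) != n || length(event) != n)
    abort_data("X, time, and event have differing lengths")
  if (length(time) && any(!is.finite(time) | time <= 0))
    abort_data("follow-up times must be finite and > 0")
  if (length(event) && !all(event %in% c(0, 1)))
    abort_data("event indicator must be coded 0/1")
  if (length(beta) != p)
    abort_data(sprintf("beta has length %d but the model has p = %d columns",
                       length(beta), p))

  zero <- function() score_info("cox", n = n, n_events = sum(event),
                                gradient = numeric(p),
                                information = matrix(0, p, p),
                                loglik = 0, iteration = iteration,
                                partner_id = partner_id)
  if (n == 0L || sum(event) == 0) return(zero())

  ord <- order(time)
  x <- X[ord, , drop = FALSE]
  tt <- time[ord]
  ev <- event[ord]
  eta <- drop(x %*% beta)
  w <- exp(eta)

  rev_cumsum <- function(v) rev(cumsum(rev(v)))
  S0 <- rev_cumsum(w)
  wx <- x * w
  S1 <- apply(wx, 2, rev_cumsum)
  if (n == 1L) S1 <- matrix(S1, 1L, p)
  # upper-triangular cross products, reverse-accumulated
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  wxx <- wx[, ut[, 1L], drop = FALSE] * x[, ut[, 2L], drop = FALSE]
  S2 <- apply(wxx, 2, rev_cumsum)
  if (n == 1L) S2 <- matrix(S2, 1L, nrow(ut))

  et <- tt[ev == 1]
  ue <- unique(et)
  idx <- match(ue, tt)                       # first at-risk row for each event time
  d <- as.numeric(table(factor(et, levels = ue)))
  sum_x_events <- rowsum(x[ev == 1, , drop = FALSE], group = factor(et, levels = ue))

  S0e <- S0[idx]
  xbar <- S1[idx, , drop = FALSE] / S0e
  ll <- sum(eta[ev == 1]) - sum(d * log(S0e))
  grad <- colSums(sum_x_events) - colSums(d * xbar)

  A_ut <- colSums(d * S2[idx, , drop = FALSE] / S0e)
  A <- matrix(0, p, p)
  A[ut] <- A_ut
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  info <- A - crossprod(sqrt(d) * xbar)

  score_info("cox", n = n, n_events = sum(ev),
             gradient = grad, information = info, loglik = ll,
             iteration = iteration, partner_id = partner_id)
}
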