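#' Local score, information, and log-likelihood for logistic regression
#'
#' Evaluated at the parameter vector currently distributed by the
#' analysis center.  With fitted probabilities `pi = expit(X beta)` the
#' statistics are the standard maximum-likelihood quantities:
#' score `X'(y - pi)`, observed (= expected) information `X' W X` with
#' `W = diag(pi (1 - pi))`, and the Bernoulli log-likelihood.  All three
#' are additive across partners at a fixed beta, which is what makes the
#' distributed Newton-Raphson update exactly equal to the pooled one.
#'
#' The log-likelihood is computed on the linear-predictor scale
#' (`y*eta - log(1 + exp(eta))` with the usual overflow guard), so it
#' stays finite even when a trial beta drives probabilities to 0 or 1.
#'
#' @param X n-by-p model matrix.
#' @param y 0/1 outcome vector.
#' @param beta Parameter vector of length p.
#' @param iteration,partner_id Protocol bookkeeping echoed in the payload.
#' @return A `dra_score_info` payload.
#' @export
logistic_local_score_info <- function(X, y, beta,
                                      iteration = 1L, partner_id = NA_integer_) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort_data("X and y have differing numbers of rows")
  if (length(y) && !all(y %in% c(0, 1)))
    abort_data("logistic outcome must be coded 0/1")
  if (length(beta) != ncol(X))
    abort_data(sprintf("beta has length %d but the model has p = %d columns",
                       length(beta), ncol(X)))
  p <- ncol(X)
  if (nrow(X) == 0L) {
    si <- score_info("logistic", n = 0L, n_events = 0L,
                     gradient = numeric(p), information = matrix(0, p, p),
                     loglik = 0, iteration = iteration, partner_id = partner_id)
    return(si)
  }
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pi * (1 - pi)
  # log(1 + exp(eta)) without overflow for large |eta|
  log1pe <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  ll <- sum(y * eta - log1pe)
  info <- crossprod(X * sqrt(w))
  score_info("logistic",
             n = nrow(X), n_events = sum(y),
             gradient = drop(crossprod(X, y - pi)),
             information = info,
             loglik = ll, iteration = iteration, partner_id = partner_id)
}

# shared constructor for score/information payloads (logistic + cox)
score_info <- function(family, n, n_events, gradient, information, loglik,
                       iteration, partner_id) {
  information <- unname((information + t(information)) / 2)
  out <- list(
    kind = "score_info", family = family,
    iteration = as.integer(iteration), partner_id = as.integer(partner_id),
    p = length(gradient),
    n = as.integer(n), n_events = as.integer(round(n_events)),
    gradient = unname(as.numeric(gradient)),
    information = information,
    loglik = as.numeric(loglik)
  )
  class(out) <- c("dra_score_info", "dra_payload")
  out
}
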