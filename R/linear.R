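#' Local sums of squares and cross products for linear regression
#'
#' The partner-side statistic for distributed linear regression: the
#' cross-product blocks `X'X`, `X'y`, `y'y` and the row count.  These are
#' additive across partners, so the center recovers the pooled
#' least-squares normal equations by elementwise summation — no second
#' round trip is needed and the fit completes in a single iteration.
#'
#' @param X n-by-p model matrix.
#' @param y Numeric outcome vector of length n.
#' @param iteration,partner_id Protocol bookkeeping echoed in the payload.
#' @return A `dra_linear_summaries` payload.
#' @export
linear_local_summaries <- function(X, y, iteration = 1L, partner_id = NA_integer_) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    abort_data("X and y have differing numbers of rows")
  if ((length(X) && !all(is.finite(X))) || (length(y) && !all(is.finite(y))))
    abort_data("non-finite values in model matrix or outcome")
  p <- ncol(X)
  out <- list(
    kind = "linear_summaries",
    family = "linear",
    iteration = as.integer(iteration),
    partner_id = as.integer(partner_id),
    p = p,
    n = nrow(X),
    xtx = if (nrow(X)) crossprod(X) else matrix(0, p, p),
    xty = if (nrow(X)) drop(crossprod(X, y)) else numeric(p),
    yty = sum(y * y)
  )
  out$xtx <- unname((out$xtx + t(out$xtx)) / 2)  # enforce exact symmetry
  out$xty <- unname(out$xty)
  class(out) <- c("dra_linear_summaries", "dra_payload")
  out
}

#' Solve the pooled normal equations from aggregated summaries
#'
#' Center-side, single-shot estimation for the linear family.  With
#' aggregated `xtx`, `xty`, `yty` and total `n`, the pooled
#' ordinary-least-squares estimate solves `xtx %*% beta = xty`; the
#' residual variance follows from the quadratic expansion of the residual
#' sum of squares, so no patient-level residual is ever needed:
#' `sigma2 = (yty - 2 b'xty + b' xtx b) / (n - p)`.
#'
#' Rank deficiency is a hard error (no silent pseudo-inverse): in a
#' distributed run collinearity must be diagnosed, not papered over.
#'
#' @param total Aggregated `dra_linear_summaries`.
#' @param terms Optional coefficient names.
#' @return A [`dra_fit`][print.dra_fit] result with `n_iterations = 1`.
#' @export
linear_solve <- function(total, terms = NULL) {
  stopifnot(inherits(total, "dra_linear_summaries"))
  p <- total$p
  if (total$n <= p)
    abort_estimation(sprintf(
      "insufficient data: n = %d patients for p = %d parameters", total$n, p))
  R <- chol_spd(total$xtx, paste0(
    "aggregated X'X is rank deficient (collinear covariates); ",
    "refusing pseudo-inverse"))
  beta <- drop(backsolve(R, backsolve(R, total$xty, transpose = TRUE)))
  rss <- total$yty - 2 * sum(beta * total$xty) +
    drop(crossprod(beta, total$xtx %*% beta))
  sigma2 <- rss / (total$n - p)
  inf <- wald_inference("linear", beta, total$xtx, sigma2 = sigma2)
  new_fit_result(
    family = "linear", beta_hat = beta, cov = inf$cov, se = inf$se,
    wald_z = inf$wald_z, ci95 = inf$ci95, loglik_final = NA_real_,
    sigma2 = sigma2, n_total = total$n, n_events_total = NA_integer_,
    n_iterations = 1L, converged = TRUE,
    history = data.frame(iteration = 1L, loglik = NA_real_,
                         max_abs_delta = 0, halvings = 0L),
    beta_history = list(beta), terms = terms
  )
}
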