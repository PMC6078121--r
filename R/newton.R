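#' Aggregate partner payloads into pooled intermediate statistics
#'
#' Elementwise summation of the partners' local statistics at a fixed
#' parameter vector.  All payloads must agree on family, parameter count,
#' and iteration index; payloads are summed in ascending partner id so
#' repeated runs are bit-reproducible regardless of arrival order.
#'
#' @param payloads List of `dra_score_info` or `dra_linear_summaries`
#'   payloads, one per partner.
#' @return A payload of the same class with summed components and
#'   `partner_id = NA`.
#' @export
aggregate_statistics <- function(payloads) {
  if (!length(payloads)) abort_protocol("no payloads to aggregate")
  kinds <- vapply(payloads, `[[`, "", "kind")
  fams  <- vapply(payloads, `[[`, "", "family")
  ps    <- vapply(payloads, `[[`, 0L, "p")
  its   <- vapply(payloads, `[[`, 0L, "iteration")
  ids   <- vapply(payloads, `[[`, 0L, "partner_id")
  if (length(unique(kinds)) != 1L || length(unique(fams)) != 1L)
    abort_protocol("payloads mix statistic kinds or model families")
  if (length(unique(ps)) != 1L)
    abort_protocol(sprintf(
      "parameter-count mismatch: partner(s) %s sent p = %s, expected %d",
      paste(ids[ps != ps[1L]], collapse = ", "),
      paste(unique(ps[ps != ps[1L]]), collapse = ", "), ps[1L]))
  if (length(unique(its)) != 1L) {
    ref <- min(its)
    abort_protocol(sprintf(
      "iteration-index mismatch: partner(s) %s answered iteration %s, expected %d",
      paste(ids[its != ref], collapse = ", "),
      paste(its[its != ref], collapse = ", "), ref))
  }
  payloads <- payloads[order(ids)]              # deterministic summation order
  out <- payloads[[1L]]
  sum_field <- function(name) Reduce(`+`, lapply(payloads, `[[`, name))
  out$n <- as.integer(sum_field("n"))
  if (out$kind == "score_info") {
    out$n_events <- as.integer(sum_field("n_events"))
    out$gradient <- sum_field("gradient")
    out$information <- sum_field("information")
    out$loglik <- sum_field("loglik")
  } else {
    out$xtx <- sum_field("xtx")
    out$xty <- sum_field("xty")
    out$yty <- sum_field("yty")
  }
  out$partner_id <- NA_integer_
  out
}

# Cholesky with an explicit rank guard: chol() does not reliably fail on
# exactly singular matrices, so near-zero pivots are rejected here.
chol_spd <- function(m, what) {
  R <- tryCatch(chol(m), error = function(e) NULL)
  d <- if (is.null(R)) 0 else diag(R)
  if (is.null(R) || !all(is.finite(R)) || !all(d > 0) ||
      min(d) < 1e-7 * max(d))
    abort_estimation(what)
  R
}

#' One Newton-Raphson update from aggregated statistics
#'
#' Returns the full Newton candidate
#' `beta + solve(information, gradient)`.  Whether the candidate is
#' accepted is decided by the caller after the next round of aggregated
#' log-likelihoods is available: in a distributed run, evaluating the
#' objective at the candidate costs a protocol round trip, so
#' step-halving is driven by the analysis center, not here.
#'
#' @param beta Current parameter vector.
#' @param total Aggregated `dra_score_info`.
#' @return List with `beta_new` and `halvings = 0`.
#' @export
newton_step <- function(beta, total) {
  stopifnot(inherits(total, "dra_score_info"))
  R <- chol_spd(total$information,
                paste0("aggregated information matrix is singular; check for ",
                       "collinear covariates or complete separation"))
  step <- drop(backsolve(R, backsolve(R, total$gradient, transpose = TRUE)))
  list(beta_new = beta + step, halvings = 0L)
}

#' Assess convergence of the distributed Newton-Raphson iteration
#'
#' The run converges when the largest absolute coefficient change falls
#' at or below `tolerance`; otherwise it stops once `iteration` reaches
#' `max_iterations`.  A non-finite candidate yields state `"failed"`
#' rather than an exception, so the center can shut the protocol down
#' cleanly and report the diagnosis.
#'
#' @param beta_old,beta_new Parameter vectors of equal length.
#' @param loglik_old,loglik_new Aggregated log-likelihoods (`NA` for the
#'   linear family).
#' @param tolerance Convergence threshold on `max(abs(beta_new - beta_old))`.
#' @param max_iterations Iteration cap.
#' @param iteration Index of the iteration that produced `beta_new`.
#' @return A `dra_convergence` status list with fields `state`
#'   (`continuing`, `converged`, `max_iterations_reached`, `failed`),
#'   `iteration`, `max_abs_delta`, `loglik_delta`, and `message`.
#' @export
assess_convergence <- function(beta_old, beta_new, loglik_old, loglik_new,
                               tolerance, max_iterations, iteration) {
  if (length(beta_old) != length(beta_new))
    abort_config("beta_old and beta_new have different lengths")
  stopifnot_scalar_number(tolerance, "tolerance", positive = TRUE)
  delta <- max(abs(beta_new - beta_old))
  lld <- if (is.na(loglik_old) || is.na(loglik_new)) NA_real_
         else loglik_new - loglik_old
  state <- if (!all(is.finite(beta_new))) "failed"
           else if (delta <= tolerance) "converged"
           else if (iteration >= max_iterations) "max_iterations_reached"
           else "continuing"
  msg <- if (state == "failed")
    "non-finite parameter update; model may be separated or ill-conditioned"
  else ""
  structure(list(state = state, iteration = as.integer(iteration),
                 max_abs_delta = delta, loglik_delta = lld, message = msg),
            class = "dra_convergence")
}

#' Wald covariance, standard errors, and confidence intervals
#'
#' The covariance is the inverse aggregated information (logistic, Cox)
#' or `sigma2 * solve(xtx)` (linear).  95% limits use the fixed normal
#' multiplier 1.959964 for every family.
#'
#' @param family Model family.
#' @param beta_hat Estimates.
#' @param information Aggregated information matrix, or `X'X` for linear.
#' @param sigma2 Residual variance (linear only).
#' @return List with `cov`, `se`, `wald_z`, `ci95` (p-by-2 matrix).
#' @export
wald_inference <- function(family, beta_hat, information, sigma2 = NULL) {
  z975 <- 1.959964
  R <- chol_spd(information,
                "information (or X'X) matrix is singular; Wald inference unavailable")
  cov <- chol2inv(R)
  if (family == "linear") {
    stopifnot_scalar_number(sigma2, "sigma2")
    cov <- sigma2 * cov
  }
  se <- sqrt(diag(cov))
  ci <- cbind(lower = beta_hat - z975 * se, upper = beta_hat + z975 * se)
  list(cov = cov, se = se, wald_z = beta_hat / se, ci95 = ci)
}

new_fit_result <- function(family, beta_hat, cov, se, wald_z, ci95,
                           loglik_final, sigma2, n_total, n_events_total,
                           n_iterations, converged, history, beta_history,
                           terms = NULL, state = if (converged) "converged" else "max_iterations_reached",
                           message = "") {
  if (!is.null(terms)) {
    names(beta_hat) <- terms
    names(se) <- terms
    rownames(ci95) <- terms
    dimnames(cov) <- list(terms, terms)
  }
  structure(list(
    family = family, beta_hat = beta_hat, cov = cov, se = se,
    wald_z = wald_z, ci95 = ci95, loglik_final = loglik_final,
    sigma2 = sigma2, n_total = n_total, n_events_total = n_events_total,
    n_iterations = n_iterations, converged = converged, state = state,
    message = message, history = history, beta_history = beta_history
  ), class = "dra_fit")
}

#' @export
print.dra_fit <- function(x, digits = 6, ...) {
  cat(sprintf("Distributed %s regression fit\n", x$family))
  cat(sprintf("  n = %d%s, iterations = %d, %s\n",
              x$n_total,
              if (!is.na(x$n_events_total))
                sprintf(" (%d events)", x$n_events_total) else "",
              x$n_iterations, x$state))
  if (!is.na(x$loglik_final))
    cat(sprintf("  log-likelihood = %.*f\n", 4, x$loglik_final))
  if (!is.na(x$sigma2))
    cat(sprintf("  residual variance = %.*g\n", digits, x$sigma2))
  tab <- data.frame(estimate = x$beta_hat, se = x$se, z = x$wald_z,
                    lower95 = x$ci95[, 1L], upper95 = x$ci95[, 2L])
  print(round(tab, digits))
  invisible(x)
}

# Shared Newton-Raphson driver.  `evaluate(beta, dist_index)` must return
# the aggregated dra_score_info at beta; in a file-based run that is one
# full distribute/collect round trip, in memory it is a plain sum over
# partners.  Every call gets a fresh strictly-increasing distribution
# index so protocol payloads can echo it.
nr_drive <- function(evaluate, p, tolerance = 1e-6, max_iterations = 25L,
                     max_halvings = 10L) {
  beta <- numeric(p)
  dist_idx <- 1L
  agg <- evaluate(beta, dist_idx)
  iter <- 1L
  history <- list(list(iteration = 1L, beta = beta, loglik = agg$loglik,
                       max_abs_delta = NA_real_, halvings = 0L))
  status <- NULL
  failed_msg <- NULL
  repeat {
    cand <- tryCatch(newton_step(beta, agg)$beta_new,
                     dra_estimation_error = function(e) e)
    if (inherits(cand, "error")) {
      status <- structure(list(state = "failed", iteration = iter,
                               max_abs_delta = NA_real_,
                               loglik_delta = NA_real_,
                               message = conditionMessage(cand)),
                          class = "dra_convergence")
      break
    }
    step <- cand - beta
    halvings <- 0L
    dist_idx <- dist_idx + 1L
    agg_c <- evaluate(cand, dist_idx)
    # step-halving: shrink until the aggregated loglik stops decreasing
    while (is.finite(agg$loglik) &&
           (!is.finite(agg_c$loglik) || agg_c$loglik < agg$loglik - 1e-12) &&
           halvings < max_halvings) {
      halvings <- halvings + 1L
      cand <- beta + step / 2^halvings
      dist_idx <- dist_idx + 1L
      agg_c <- evaluate(cand, dist_idx)
    }
    if (is.finite(agg$loglik) &&
        (!is.finite(agg_c$loglik) || agg_c$loglik < agg$loglik - 1e-12)) {
      status <- structure(list(state = "failed", iteration = iter,
                               max_abs_delta = NA_real_,
                               loglik_delta = agg_c$loglik - agg$loglik,
                               message = sprintf(
                                 "log-likelihood still decreasing after %d step halvings",
                                 max_halvings)),
                          class = "dra_convergence")
      break
    }
    iter <- iter + 1L
    status <- assess_convergence(beta, cand, agg$loglik, agg_c$loglik,
                                 tolerance, max_iterations, iter)
    beta <- cand
    agg <- agg_c
    history[[iter]] <- list(iteration = iter, beta = beta, loglik = agg$loglik,
                            max_abs_delta = status$max_abs_delta,
                            halvings = halvings)
    if (status$state != "continuing") break
  }
  list(beta = beta, agg = agg, status = status, history = history,
       n_distributions = dist_idx, n_iterations = iter)
}

history_frame <- function(history) {
  data.frame(
    iteration = vapply(history, `[[`, 0L, "iteration"),
    loglik = vapply(history, `[[`, 0, "loglik"),
    max_abs_delta = vapply(history, function(h) as.numeric(h$max_abs_delta), 0),
    halvings = vapply(history, `[[`, 0L, "halvings")
  )
}

assemble_iterative_fit <- function(family, drive, total_information, terms,
                                   n_total, n_events_total) {
  ok <- drive$status$state %in% c("converged", "max_iterations_reached")
  if (!ok) {
    inf <- list(cov = matrix(NA_real_, length(drive$beta), length(drive$beta)),
                se = rep(NA_real_, length(drive$beta)),
                wald_z = rep(NA_real_, length(drive$beta)),
                ci95 = matrix(NA_real_, length(drive$beta), 2L))
  } else {
    inf <- wald_inference(family, drive$beta, total_information)
  }
  new_fit_result(
    family = family, beta_hat = drive$beta, cov = inf$cov, se = inf$se,
    wald_z = inf$wald_z, ci95 = inf$ci95,
    loglik_final = drive$agg$loglik, sigma2 = NA_real_,
    n_total = drive$agg$n, n_events_total = n_events_total,
    n_iterations = drive$n_iterations,
    converged = drive$status$state == "converged",
    history = history_frame(drive$history),
    beta_history = lapply(drive$history, `[[`, "beta"),
    terms = terms, state = drive$status$state, message = drive$status$message
  )
}

#' Fit a distributed regression in memory
#'
#' Runs the same aggregation and Newton-Raphson machinery as the
#' file-based protocol, but with the per-partner datasets held in one
#' process: at each iteration every partner's local statistics are
#' computed at the current beta, summed in ascending partner order, and
#' the center update is applied.  Because the local statistics are
#' additive, the result is identical to the pooled fit (site-stratified
#' for Cox) and to a full file-based run on the same data.
#'
#' This is the engine used for simulation studies, where the file
#' transport would only add I/O; the file-based orchestrator
#' [dra_run()] calls the identical update code.
#'
#' @param datasets List of per-partner data frames (ascending partner id).
#' @param spec A [design_spec()].
#' @param tolerance,max_iterations Newton-Raphson controls.
#' @return A `dra_fit` result.
#' @examples
#' cs <- standard_cohort_spec("logistic")
#' ds <- lapply(1:3, function(k) generate_partner_dataset(cs, k))
#' fit <- dra_fit(ds, design_spec("logistic", c("x1", "x2", "x3")))
#' fit$beta_hat
#' @export
dra_fit <- function(datasets, spec, tolerance = 1e-6, max_iterations = 25L) {
  stopifnot(is.list(datasets), length(datasets) >= 1L,
            inherits(spec, "dra_design"))
  mm <- lapply(datasets, build_model_matrix, spec = spec)
  p <- design_p(spec)
  terms <- design_terms(spec)
  if (spec$family == "linear") {
    payloads <- lapply(seq_along(mm), function(k)
      linear_local_summaries(mm[[k]]$X, mm[[k]]$y, iteration = 1L,
                             partner_id = k))
    return(linear_solve(aggregate_statistics(payloads), terms = terms))
  }
  evaluate <- function(beta, idx) {
    payloads <- lapply(seq_along(mm), function(k) {
      m <- mm[[k]]
      if (spec$family == "logistic")
        logistic_local_score_info(m$X, m$y, beta, iteration = idx, partner_id = k)
      else
        cox_local_score_info(m$X, m$time, m$event, beta, iteration = idx,
                             partner_id = k)
    })
    aggregate_statistics(payloads)
  }
  drive <- nr_drive(evaluate, p, tolerance, max_iterations)
  assemble_iterative_fit(spec$family, drive, drive$agg$information, terms,
                         n_total = drive$agg$n,
                         n_events_total = drive$agg$n_events)
}
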