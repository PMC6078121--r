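new_diagnostics_payload <- function(family, iteration, partner_id, p, n,
                                    n_events, loglik_final, bin_edges,
                                    bin_n, bin_sum_y, bin_sum_p) {
  structure(list(kind = "diagnostics", family = family,
                 iteration = as.integer(iteration),
                 partner_id = as.integer(partner_id),
                 p = as.integer(p), n = as.integer(n),
                 n_events = as.integer(n_events),
                 loglik_final = as.numeric(loglik_final),
                 n_bins = length(bin_n),
                 bin_edges = as.numeric(bin_edges),
                 bin_n = as.numeric(bin_n),
                 bin_sum_y = as.numeric(bin_sum_y),
                 bin_sum_p = as.numeric(bin_sum_p)),
            class = c("dra_diagnostics_payload", "dra_payload"))
}

#' Default probability bin edges for distributed diagnostics
#'
#' Equal-width edges spanning \[0, 1\].  Fixed global edges (rather than
#' pooled deciles of risk) are used so partners can bin locally without a
#' second protocol round to agree on cut points.
#'
#' @param n_bins Number of bins (default 20).
#' @return Numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
default_bin_edges <- function(n_bins = 20L) {
  seq(0, 1, length.out = n_bins + 1L)
}

#' Partner-side diagnostics from the converged fit
#'
#' After the terminal `job_done` broadcast each partner evaluates the
#' final model on its own patients and returns only binned aggregates:
#' per predicted-probability bin, the patient count, the sum of observed
#' outcomes, and the sum of predicted probabilities, plus the final local
#' log-likelihood.  These aggregates are additive across partners and
#' are exactly sufficient for a pooled binned goodness-of-fit statistic
#' and a binned area under the ROC curve, while their size depends only
#' on the bin count — never on the patient count.
#'
#' For the Cox family the payload carries the final local stratified
#' partial log-likelihood and event count (bins empty); for the linear
#' family it carries the local residual sum of squares in
#' `loglik_final`'s place alongside `n`.
#'
#' @param mm Model arrays from [build_model_matrix()].
#' @param family Model family.
#' @param beta_final Converged parameter vector.
#' @param bin_edges Global bin edges (logistic only), e.g.
#'   [default_bin_edges()].
#' @param iteration,partner_id Protocol bookkeeping.
#' @return A `dra_diagnostics_payload`.
#' @export
local_diagnostics <- function(mm, family, beta_final,
                              bin_edges = default_bin_edges(),
                              iteration = 1L, partner_id = NA_integer_) {
  p <- ncol(mm$X)
  if (length(beta_final) != p)
    abort_data("beta_final length does not match the model matrix")
  if (family == "logistic") {
    if (is.unsorted(bin_edges, strictly = TRUE) ||
        abs(bin_edges[1L]) > 1e-12 ||
        abs(bin_edges[length(bin_edges)] - 1) > 1e-12)
      abort_config("bin_edges must be strictly increasing and span [0, 1]")
    eta <- drop(mm$X %*% beta_final)
    pi <- stats::plogis(eta)
    if (any(pi < 0 | pi > 1))
      dra_abort("predicted probability outside [0, 1]; upstream corruption",
                "dra_internal_error")
    nb <- length(bin_edges) - 1L
    bin <- findInterval(pi, bin_edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    f <- factor(bin, levels = seq_len(nb))
    log1pe <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    new_diagnostics_payload(
      family = "logistic", iteration = iteration, partner_id = partner_id,
      p = p, n = nrow(mm$X), n_events = sum(mm$y),
      loglik_final = sum(mm$y * eta - log1pe),
      bin_edges = bin_edges,
      bin_n = as.numeric(table(f)),
      bin_sum_y = as.numeric(tapply(mm$y, f, sum, default = 0)),
      bin_sum_p = as.numeric(tapply(pi, f, sum, default = 0)))
  } else if (family == "cox") {
    si <- cox_local_score_info(mm$X, mm$time, mm$event, beta_final,
                               iteration = iteration, partner_id = partner_id)
    new_diagnostics_payload(
      family = "cox", iteration = iteration, partner_id = partner_id,
      p = p, n = si$n, n_events = si$n_events, loglik_final = si$loglik,
      bin_edges = numeric(0), bin_n = numeric(0),
      bin_sum_y = numeric(0), bin_sum_p = numeric(0))
  } else {
    resid <- mm$y - drop(mm$X %*% beta_final)
    new_diagnostics_payload(
      family = "linear", iteration = iteration, partner_id = partner_id,
      p = p, n = nrow(mm$X), n_events = 0L,
      loglik_final = sum(resid^2),        # local residual sum of squares
      bin_edges = numeric(0), bin_n = numeric(0),
      bin_sum_y = numeric(0), bin_sum_p = numeric(0))
  }
}

#' Pool partner diagnostics into calibration and discrimination summaries
#'
#' Logistic: a Hosmer-Lemeshow-type statistic over the nonempty pooled
#' bins, `sum((O - E)^2 / (E (1 - E/n)))` with `O` the summed outcomes
#' and `E` the summed predicted probabilities per bin, on
#' `nonempty bins - 2` degrees of freedom; and a binned AUC — the
#' probability that a random case falls in a higher bin than a random
#' control, counting ties as one half — computed from pooled per-bin
#' case/control counts.  Because the per-bin aggregates are additive,
#' both statistics are identical to the same binned computation on the
#' pooled patient-level data.
#'
#' Cox: total stratified partial log-likelihood and event count.
#' Linear: pooled residual sum of squares.
#'
#' @param payloads List of `dra_diagnostics_payload`, one per partner.
#' @return A list report; for logistic it contains `hl_statistic`,
#'   `hl_df`, `hl_p_value`, `auc_binned`, `loglik_final`, `n`, `n_events`.
#' @export
aggregate_diagnostics <- function(payloads) {
  if (!length(payloads)) abort_protocol("no diagnostics payloads")
  fams <- vapply(payloads, `[[`, "", "family")
  if (length(unique(fams)) != 1L)
    abort_protocol("diagnostics payloads mix model families")
  family <- fams[1L]
  ids <- vapply(payloads, `[[`, 0L, "partner_id")
  payloads <- payloads[order(ids)]
  n <- sum(vapply(payloads, `[[`, 0L, "n"))
  ll <- sum(vapply(payloads, `[[`, 0, "loglik_final"))
  if (family == "linear")
    return(list(family = family, n = n, rss = ll))
  n_events <- sum(vapply(payloads, `[[`, 0L, "n_events"))
  if (family == "cox")
    return(list(family = family, n = n, n_events = n_events,
                loglik_final = ll))

  edges <- payloads[[1L]]$bin_edges
  same <- vapply(payloads, function(pl)
    length(pl$bin_edges) == length(edges) &&
      all(abs(pl$bin_edges - edges) < 1e-12), TRUE)
  if (!all(same))
    abort_protocol(sprintf("bin-edge mismatch from partner(s) %s",
                           paste(ids[!same], collapse = ", ")))
  bin_n <- Reduce(`+`, lapply(payloads, `[[`, "bin_n"))
  O <- Reduce(`+`, lapply(payloads, `[[`, "bin_sum_y"))
  E <- Reduce(`+`, lapply(payloads, `[[`, "bin_sum_p"))

  keep <- bin_n > 0
  hl <- sum((O[keep] - E[keep])^2 / (E[keep] * (1 - E[keep] / bin_n[keep])))
  hl_df <- max(sum(keep) - 2L, 0L)
  hl_p <- if (hl_df > 0) stats::pchisq(hl, hl_df, lower.tail = FALSE)
          else NA_real_

  cases <- O
  controls <- bin_n - O
  tc <- sum(cases)
  tn <- sum(controls)
  auc <- if (tc == 0 || tn == 0) NA_real_ else {
    # controls in strictly lower bins + half the same-bin ties
    cum_controls <- c(0, cumsum(controls))[seq_along(controls)]
    (sum(cases * cum_controls) + 0.5 * sum(cases * controls)) / (tc * tn)
  }
  list(family = "logistic", n = n, n_events = n_events,
       loglik_final = ll, hl_statistic = hl, hl_df = hl_df,
       hl_p_value = hl_p, auc_binned = auc, bin_edges = edges,
       bin_n = bin_n, bin_sum_y = O, bin_sum_p = E)
}
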