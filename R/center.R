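# The analysis center: broadcasts parameter states, collects and
# aggregates partner payloads, drives the Newton-Raphson update with
# step-halving, and assembles the final fit.

#' Create an analysis-center node
#'
#' @param layout A [folder_layout()].
#' @param spec A [design_spec()].
#' @param gate An [approval_gate()].
#' @param tolerance,max_iterations Newton-Raphson controls.
#' @param poll_interval,timeout Per-collection polling controls (seconds).
#' @param bin_edges Diagnostics bin edges distributed with the terminal
#'   broadcast.
#' @return A `dra_center` node (mutable environment).
#' @export
center_node <- function(layout, spec, gate = approval_gate(),
                        tolerance = 1e-6, max_iterations = 25L,
                        poll_interval = 0.5, timeout = 300,
                        bin_edges = default_bin_edges()) {
  stopifnot(inherits(layout, "dra_layout"), inherits(spec, "dra_design"))
  stopifnot_scalar_number(tolerance, "tolerance", positive = TRUE)
  if (max_iterations < 1L) abort_config("max_iterations must be >= 1")
  node <- new.env(parent = emptyenv())
  node$layout <- layout
  node$spec <- spec
  node$gate <- gate
  node$tolerance <- tolerance
  node$max_iterations <- as.integer(max_iterations)
  node$poll_interval <- poll_interval
  node$timeout <- timeout
  node$bin_edges <- bin_edges
  node$archive_seq <- 0L
  node$n_broadcasts <- 0L
  node$beta_history <- list()
  class(node) <- "dra_center"
  node
}

log_line <- function(path, node_name, event, iteration = NA, detail = "") {
  line <- sprintf("%s | %s | %s | iteration=%s | %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
                  node_name, event, as.character(iteration), detail)
  cat(line, "\n", sep = "", file = path, append = TRUE)
}

next_archive_dir <- function(center, direction, partner_id) {
  center$archive_seq <- center$archive_seq + 1L
  file.path(center$layout$center$archive,
            sprintf("%04d_%s_partner%d", center$archive_seq, direction,
                    partner_id))
}

#' Broadcast a parameter state to every data partner
#'
#' Writes the parameter file once and deposits an identical copy, plus
#' the trigger (`files_done.ok`, or `job_done.ok` for the terminal
#' state), into every partner's `inputfiles` folder.  Every deposit is
#' archived and recorded in the audit log; any deposit failure aborts
#' the run.
#'
#' @param center A [center_node()].
#' @param bs A [beta_state()].
#' @return List of transfer records, invisibly.
#' @export
distribute_parameters <- function(center, bs) {
  stopifnot(inherits(center, "dra_center"), inherits(bs, "dra_beta_state"))
  layout <- center$layout
  if (layout$n_partners < 1L) abort_config("no partners configured")
  staging <- file.path(layout$center$inputfiles,
                       sprintf("parameters_iter%03d.txt", bs$iteration))
  write_payload(bs, staging)
  trigger <- if (bs$job_done) "job_done" else "files_done"
  records <- lapply(seq_len(layout$n_partners), function(k) {
    deposit(staging, layout$partners[[k]]$inputfiles, trigger,
            gate = center$gate, direction = "center_to_partner",
            partner_id = k, iteration = bs$iteration,
            log_path = layout$center$audit_log,
            archive_dir = next_archive_dir(center, "center_to_partner", k))
  })
  center$n_broadcasts <- center$n_broadcasts + 1L
  log_line(layout$center$run_log, "center",
           if (bs$job_done) "broadcast_job_done" else "broadcast_parameters",
           bs$iteration, sprintf("trigger=%s", trigger_filename(trigger)))
  invisible(records)
}

#' Collect one iteration's payloads from all partners
#'
#' For each partner in ascending id order: poll the partner's `msoc`
#' folder for its `files_done.ok` trigger, relay the files into the
#' center's per-partner inbox (`msoc1` ... `msocK`) — the gated step at
#' which files leave the partner's site — and consume them from the
#' inbox into the center workspace.  Requires a response from every
#' partner; lagging partners are named in the failure.  A structured
#' error payload from any partner fails the run with that partner's
#' message.
#'
#' @param center A [center_node()].
#' @param expected_iteration Iteration index the payloads must echo.
#' @param kinds Acceptable payload kinds.
#' @return List of payloads, one per partner, ascending partner id.
#' @export
collect_intermediates <- function(center, expected_iteration,
                                  kinds = c("score_info", "linear_summaries")) {
  layout <- center$layout
  seen <- vapply(seq_len(layout$n_partners), function(k)
    poll_for_trigger(layout$partners[[k]]$msoc, "files_done",
                     interval = center$poll_interval,
                     timeout = center$timeout), TRUE)
  if (!all(seen))
    abort_transfer(sprintf(
      "timed out waiting for intermediate statistics from partner(s): %s",
      paste(which(!seen), collapse = ", ")))
  payloads <- lapply(seq_len(layout$n_partners), function(k) {
    staged <- consume(layout$partners[[k]]$msoc, "files_done",
                      file.path(layout$center$work, sprintf("relay%d", k)),
                      gate = center$gate, direction = "partner_to_center",
                      partner_id = k, leaving_partner_msoc = TRUE)
    deposit(staged, layout$center$inbox[k], "files_done",
            gate = center$gate, direction = "partner_to_center",
            partner_id = k, iteration = expected_iteration,
            log_path = layout$center$audit_log,
            archive_dir = next_archive_dir(center, "partner_to_center", k))
    file.remove(staged)
    got <- consume(layout$center$inbox[k], "files_done",
                   file.path(layout$center$work, sprintf("inbox%d", k)),
                   gate = center$gate, direction = "partner_to_center",
                   partner_id = k)
    if (!length(got))
      abort_protocol(sprintf("partner %d signalled but sent no payload", k))
    pl <- read_payload(got[[1L]])
    if (identical(pl$kind, "error"))
      abort_protocol(sprintf("partner %d reported an error: %s", k,
                             pl$message))
    if (!pl$kind %in% kinds)
      abort_protocol(sprintf("partner %d sent unexpected payload kind '%s'",
                             k, pl$kind))
    if (pl$iteration != expected_iteration)
      abort_protocol(sprintf(
        "partner %d answered iteration %d, expected %d", k, pl$iteration,
        expected_iteration))
    pl
  })
  log_line(layout$center$run_log, "center", "collected", expected_iteration,
           sprintf("partners=%d", length(payloads)))
  payloads
}

#' Run the analysis center to completion
#'
#' Drives the full protocol: broadcast the initial zero parameter
#' vector, collect and aggregate partner statistics, apply the
#' Newton-Raphson update with center-driven step-halving (each halved
#' step costs one extra broadcast/collect round trip), assess
#' convergence, and — once converged, iteration-capped, or failed —
#' broadcast the terminal `job_done` state, collect partner diagnostics,
#' and assemble the [`dra_fit`][print.dra_fit] with its aggregated
#' diagnostics report.
#'
#' `pump`, when supplied, is called after every broadcast; the
#' single-process orchestrator uses it to let each partner node serve
#' the pending message, which makes the run deterministic without
#' background processes.  With real concurrent partners, leave it
#' `NULL`.
#'
#' @param center A [center_node()].
#' @param pump Optional `function()` run after each broadcast.
#' @return List with `fit`, `diagnostics`, `status`, `n_broadcasts`.
#' @export
run_center <- function(center, pump = NULL) {
  stopifnot(inherits(center, "dra_center"))
  spec <- center$spec
  p <- design_p(spec)
  terms <- design_terms(spec)
  dist_counter <- new.env(parent = emptyenv())
  dist_counter$idx <- 0L

  evaluate <- function(beta, idx, job_done = FALSE) {
    bs <- beta_state(beta, idx, spec$family, job_done = job_done)
    distribute_parameters(center, bs)
    if (!is.null(pump)) pump()
    kinds <- if (job_done) "diagnostics"
             else if (spec$family == "linear") "linear_summaries"
             else "score_info"
    payloads <- collect_intermediates(center, idx, kinds = kinds)
    if (job_done) payloads else aggregate_statistics(payloads)
  }

  if (spec$family == "linear") {
    agg <- evaluate(numeric(p), 1L)
    fit <- linear_solve(agg, terms = terms)
    drive <- list(beta = fit$beta_hat, n_distributions = 1L)
    status <- structure(list(state = "converged", iteration = 1L,
                             max_abs_delta = 0, loglik_delta = NA_real_,
                             message = ""), class = "dra_convergence")
  } else {
    drive <- nr_drive(function(beta, idx) {
      dist_counter$idx <- idx
      agg <- evaluate(beta, idx)
      log_line(center$layout$center$run_log, "center", "aggregated", idx,
               sprintf("loglik=%.10g", agg$loglik))
      agg
    }, p, center$tolerance, center$max_iterations)
    status <- drive$status
    fit <- assemble_iterative_fit(spec$family, drive, drive$agg$information,
                                  terms, drive$agg$n, drive$agg$n_events)
  }
  center$beta_history <- if (spec$family == "linear") list(fit$beta_hat)
                         else lapply(drive$history, `[[`, "beta")

  # terminal broadcast: partners compute diagnostics at the final beta
  # (fall back to the zero vector if the run failed with non-finite beta)
  final_beta <- if (all(is.finite(fit$beta_hat))) fit$beta_hat
                else numeric(p)
  final_idx <- if (spec$family == "linear") 2L else drive$n_distributions + 1L
  diag_report <- tryCatch({
    payloads <- evaluate(final_beta, final_idx, job_done = TRUE)
    aggregate_diagnostics(payloads)
  }, error = function(e) list(incomplete = TRUE,
                              message = conditionMessage(e)))
  finalize(center, fit, status, diag_report)
}

#' Write the run report and return the assembled result
#'
#' Persists a plain-text estimates table plus a machine-readable CSV of
#' the fit and a DCF metadata block into the center folder, and
#' cross-checks the audit log's broadcast count against the center's own
#' counter.
#'
#' @param center A [center_node()].
#' @param fit A `dra_fit`.
#' @param status Terminal `dra_convergence` status.
#' @param diagnostics Aggregated diagnostics report.
#' @return List with `fit`, `diagnostics`, `status`, `n_broadcasts`,
#'   `report_files`.
#' @export
finalize <- function(center, fit, status, diagnostics) {
  layout <- center$layout
  base <- dirname(layout$center$audit_log)
  est_csv <- file.path(base, "fit_result.csv")
  report_txt <- file.path(base, "run_report.txt")
  meta_dcf <- file.path(base, "run_meta.dcf")

  tab <- data.frame(term = names(fit$beta_hat), estimate = fit$beta_hat,
                    se = fit$se, z = fit$wald_z,
                    lower95 = fit$ci95[, 1L], upper95 = fit$ci95[, 2L],
                    row.names = NULL)
  utils::write.csv(tab, est_csv, row.names = FALSE)

  audit_broadcasts <- if (file.exists(layout$center$audit_log)) {
    log <- read_audit_log(layout$center$audit_log)
    ctp <- log[log$direction == "center_to_partner" &
                 log$status == "transferred", ]
    length(unique(ctp$iteration))
  } else 0L

  lines <- c(
    sprintf("Distributed %s regression run report", fit$family),
    sprintf("state: %s", fit$state),
    sprintf("converged: %s", fit$converged),
    sprintf("iterations: %d", fit$n_iterations),
    sprintf("broadcasts (center counter / audit log): %d / %d",
            center$n_broadcasts, audit_broadcasts),
    sprintf("n total: %d", fit$n_total),
    if (!is.na(fit$n_events_total))
      sprintf("events total: %d", fit$n_events_total),
    if (!is.na(fit$loglik_final))
      sprintf("final log-likelihood: %.10f", fit$loglik_final),
    if (!is.na(fit$sigma2))
      sprintf("residual variance: %.10g", fit$sigma2),
    "", "term,estimate,se,z,lower95,upper95",
    sprintf("%s,%.10g,%.10g,%.10g,%.10g,%.10g", tab$term, tab$estimate,
            tab$se, tab$z, tab$lower95, tab$upper95))
  writeLines(lines, report_txt)

  meta <- data.frame(family = fit$family, state = fit$state,
                     converged = fit$converged,
                     n_iterations = fit$n_iterations,
                     n_broadcasts = center$n_broadcasts,
                     audit_broadcast_iterations = audit_broadcasts,
                     n_total = fit$n_total)
  write.dcf(meta, meta_dcf)

  log_line(layout$center$run_log, "center", "finalized", fit$n_iterations,
           sprintf("state=%s", fit$state))
  list(fit = fit, diagnostics = diagnostics, status = status,
       n_broadcasts = center$n_broadcasts,
       report_files = c(report = report_txt, estimates = est_csv,
                        meta = meta_dcf))
}
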