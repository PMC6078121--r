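# One data partner: holds the dplocal analytic dataset, answers parameter
# broadcasts with local aggregate statistics, and computes diagnostics on
# the terminal job_done signal.

#' Create a data-partner node
#'
#' The node reads its analytic dataset from its `dplocal` folder (or
#' accepts one directly), and serves the protocol: wait for a trigger in
#' `inputfiles`, consume the parameter state, compute local statistics,
#' and publish them to `msoc` under a `files_done.ok` trigger.  The
#' patient-level data never leaves `dplocal`.
#'
#' @param partner_id 1-based partner index.
#' @param layout A [folder_layout()].
#' @param spec A [design_spec()].
#' @param dataset Optional data frame; by default the node reads
#'   `dplocal/analytic_dataset.csv`.
#' @param gate An [approval_gate()].
#' @param bin_edges Diagnostics bin edges (logistic).
#' @return A `dra_partner` node (mutable environment).
#' @export
partner_node <- function(partner_id, layout, spec, dataset = NULL,
                         gate = approval_gate(),
                         bin_edges = default_bin_edges()) {
  stopifnot(inherits(layout, "dra_layout"), inherits(spec, "dra_design"))
  partner_id <- as.integer(partner_id)
  if (partner_id < 1L || partner_id > layout$n_partners)
    abort_config(sprintf("partner_id must be in 1..%d", layout$n_partners))
  node <- new.env(parent = emptyenv())
  node$id <- partner_id
  node$dirs <- layout$partners[[partner_id]]
  node$spec <- spec
  node$gate <- gate
  node$bin_edges <- bin_edges
  node$dataset <- dataset
  node$mm <- NULL
  node$last_iteration_answered <- 0L
  node$served <- 0L
  node$terminated <- FALSE
  class(node) <- "dra_partner"
  node
}

partner_model_arrays <- function(node) {
  if (!is.null(node$mm)) return(node$mm)
  if (is.null(node$dataset)) {
    path <- file.path(node$dirs$dplocal, "analytic_dataset.csv")
    node$dataset <- read_dataset(path)
  }
  node$mm <- build_model_matrix(node$dataset, node$spec)
  node$mm
}

#' Compute one iteration's local intermediate statistics
#'
#' Dispatches on the model family: linear partners return the
#' beta-independent cross-product summaries (so the linear fit completes
#' in one round trip); logistic and Cox partners return score,
#' information, and log-likelihood evaluated at the supplied parameters.
#' The payload echoes the iteration index and partner id so the center
#' can detect stale or mismatched responses.
#'
#' @param node A [partner_node()].
#' @param bs A `dra_beta_state` payload.
#' @return A `dra_payload` of local statistics.
#' @export
execute_iteration <- function(node, bs) {
  mm <- partner_model_arrays(node)
  p <- design_p(node$spec)
  if (bs$p != p || length(bs$beta) != p)
    abort_protocol(sprintf(
      "parameter state has p = %d but partner %d's model has p = %d",
      bs$p, node$id, p))
  if (!identical(bs$family, node$spec$family))
    abort_protocol(sprintf("family mismatch: center sent '%s', partner fits '%s'",
                           bs$family, node$spec$family))
  switch(node$spec$family,
    linear = linear_local_summaries(mm$X, mm$y, iteration = bs$iteration,
                                    partner_id = node$id),
    logistic = logistic_local_score_info(mm$X, mm$y, bs$beta,
                                         iteration = bs$iteration,
                                         partner_id = node$id),
    cox = cox_local_score_info(mm$X, mm$time, mm$event, bs$beta,
                               iteration = bs$iteration,
                               partner_id = node$id))
}

# payload file published into the partner's own msoc folder: write under a
# temporary name, rename, then raise the trigger
publish_payload <- function(payload, folder, trigger = "files_done") {
  name <- switch(payload$kind,
    score_info = ,
    linear_summaries = sprintf("stats_partner%d_iter%03d.txt",
                               payload$partner_id, payload$iteration),
    diagnostics = sprintf("diagnostics_partner%d_iter%03d.txt",
                          payload$partner_id, payload$iteration),
    error = sprintf("error_partner%d_iter%03d.txt",
                    payload$partner_id, payload$iteration),
    abort_config(sprintf("cannot publish payload kind '%s'", payload$kind)))
  tmp <- file.path(folder, paste0(".tmp.", name))
  write_payload(payload, tmp)
  if (!file.rename(tmp, file.path(folder, name)))
    abort_transfer(sprintf("failed to publish '%s'", name))
  atomic_touch(file.path(folder, trigger_filename(trigger)))
  invisible(file.path(folder, name))
}

poll_either_trigger <- function(folder, interval, timeout) {
  if (!dir.exists(folder))
    abort_config(sprintf("monitored folder '%s' does not exist", folder))
  deadline <- Sys.time() + timeout
  repeat {
    for (kind in c("job_done", "files_done"))
      if (file.exists(file.path(folder, trigger_filename(kind)))) return(kind)
    if (Sys.time() >= deadline) return(NA_character_)
    Sys.sleep(interval)
  }
}

#' Serve at most one message from the analysis center
#'
#' Polls the partner's `inputfiles` folder; when a trigger appears,
#' consumes the parameter state and answers it.  A `job_done` state makes
#' the node compute diagnostics at the final parameters, publish them,
#' and terminate.  A malformed or stale parameter file produces a
#' structured error payload instead of statistics, so the center can
#' surface the failure; the node keeps running.
#'
#' @param node A [partner_node()].
#' @param interval,timeout Polling controls in seconds.
#' @return List with `served` (logical) and `terminal` (logical).
#' @export
partner_serve_once <- function(node, interval = 0.05, timeout = 10) {
  if (node$terminated) return(list(served = FALSE, terminal = TRUE))
  kind <- poll_either_trigger(node$dirs$inputfiles, interval, timeout)
  if (is.na(kind)) return(list(served = FALSE, terminal = FALSE))
  files <- consume(node$dirs$inputfiles, kind, node$dirs$work,
                   gate = node$gate, direction = "center_to_partner",
                   partner_id = node$id)
  publish_error <- function(msg, iteration) {
    publish_payload(error_payload(msg, node$spec$family, iteration, node$id),
                    node$dirs$msoc, "files_done")
    node$served <- node$served + 1L
    list(served = TRUE, terminal = FALSE)
  }
  bs <- tryCatch(read_payload(files[[1L]]), error = function(e) e)
  if (inherits(bs, "error") || !identical(bs$kind, "beta_state"))
    return(publish_error(
      paste("malformed parameter state:",
            if (inherits(bs, "error")) conditionMessage(bs) else bs$kind),
      iteration = node$last_iteration_answered))
  if (bs$iteration <= node$last_iteration_answered)
    return(publish_error(
      sprintf("stale iteration %d (last answered %d)", bs$iteration,
              node$last_iteration_answered),
      iteration = bs$iteration))
  if (bs$job_done || kind == "job_done") {
    payload <- tryCatch({
      mm <- partner_model_arrays(node)
      local_diagnostics(mm, node$spec$family, bs$beta,
                        bin_edges = node$bin_edges,
                        iteration = bs$iteration, partner_id = node$id)
    }, error = function(e) {
      error_payload(conditionMessage(e), node$spec$family, bs$iteration,
                    node$id)
    })
    publish_payload(payload, node$dirs$msoc, "files_done")
    node$last_iteration_answered <- bs$iteration
    node$served <- node$served + 1L
    node$terminated <- TRUE
    return(list(served = TRUE, terminal = TRUE))
  }
  payload <- tryCatch(execute_iteration(node, bs), error = function(e)
    error_payload(conditionMessage(e), node$spec$family, bs$iteration,
                  node$id))
  publish_payload(payload, node$dirs$msoc, "files_done")
  node$last_iteration_answered <- bs$iteration
  node$served <- node$served + 1L
  list(served = TRUE, terminal = FALSE)
}

#' Run a partner node until the analysis finishes
#'
#' The stand-in for the continuously running local analysis program:
#' serves parameter broadcasts until the terminal `job_done` message
#' arrives, polling stops finding work, or `max_wall_iterations`
#' messages have been served.
#'
#' @param node A [partner_node()].
#' @param max_wall_iterations Upper bound on messages served.
#' @param interval,timeout Polling controls in seconds.
#' @return Summary list: `partner_id`, `served`, `terminated`.
#' @export
run_partner_loop <- function(node, max_wall_iterations = 1000L,
                             interval = 0.05, timeout = 10) {
  while (!node$terminated && node$served < max_wall_iterations) {
    r <- partner_serve_once(node, interval = interval, timeout = timeout)
    if (!r$served) break
  }
  list(partner_id = node$id, served = node$served,
       terminated = node$terminated)
}
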