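# End-to-end orchestration: populate a folder tree with synthetic
# partner datasets, run partners + center over it in one process, and
# verify a finished run against the protocol's invariants.

manifest_path <- function(root) file.path(root, "manifest.dcf")

write_manifest <- function(root, cohort) {
  df <- data.frame(
    family = cohort$family,
    n_partners = cohort$n_partners,
    n_per_partner = paste(cohort$n_per_partner, collapse = ","),
    covariates = paste(vapply(cohort$covariates, `[[`, "", "name"),
                       collapse = ","),
    true_beta = paste(fmt17(cohort$true_beta), collapse = ","),
    seed = cohort$seed)
  write.dcf(df, manifest_path(root))
}

read_manifest <- function(root) {
  path <- manifest_path(root)
  if (!file.exists(path))
    abort_config(sprintf("no run manifest at '%s'; run dra_simulate() first",
                         path))
  m <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  m$n_partners <- as.integer(m$n_partners)
  m$covariates <- strsplit(m$covariates, ",", fixed = TRUE)[[1L]]
  m$seed <- as.integer(m$seed)
  m
}

#' Populate a run folder tree with synthetic partner datasets
#'
#' Creates the common folder structure for every partner and the center,
#' writes each partner's analytic dataset into its `dplocal` folder, and
#' records a run manifest.  Rebuilding is deterministic in the cohort
#' seed.
#'
#' @param cohort A [cohort_spec()].
#' @param root Run root directory.
#' @param force Overwrite an existing non-empty root.
#' @return The created [folder_layout()], invisibly.
#' @export
dra_simulate <- function(cohort, root, force = FALSE) {
  stopifnot(inherits(cohort, "dra_cohort_spec"))
  if (dir.exists(root) && length(list.files(root, all.files = TRUE,
                                            no.. = TRUE))) {
    if (!force)
      abort_config(sprintf(
        "root '%s' exists and is not empty; use force = TRUE to rebuild",
        root))
    unlink(root, recursive = TRUE)
  }
  layout <- folder_layout(root, cohort$n_partners)
  create_layout(layout)
  for (k in seq_len(cohort$n_partners)) {
    ds <- generate_partner_dataset(cohort, k)
    write_dataset(ds, file.path(layout$partners[[k]]$dplocal,
                                "analytic_dataset.csv"))
  }
  write_manifest(root, cohort)
  invisible(layout)
}

#' Run a full distributed regression over a simulated folder tree
#'
#' Wires one analysis-center node and one node per partner over the
#' folder tree created by [dra_simulate()] and drives the protocol to
#' completion in a single interleaved event loop: after every center
#' broadcast, each partner serves the pending message, then the center
#' collects.  Results are identical to running the nodes as separate
#' processes, because every hand-off goes through the same files and
#' triggers.
#'
#' @param root Run root created by [dra_simulate()].
#' @param tolerance,max_iterations Newton-Raphson controls.
#' @param automation `"fully_automated"`, `"semi_automated"`, or
#'   `"manual"`.
#' @param approval Optional approval callback for gated modes (see
#'   [approval_gate()]).
#' @param n_bins Diagnostics bin count.
#' @param poll_interval,timeout Polling controls in seconds.
#' @return A `dra_run_result` list: `fit`, `diagnostics`, `status`,
#'   `n_broadcasts`, `report_files`, `aborted`, `exit_code` (0 iff
#'   converged).
#' @export
dra_run <- function(root, tolerance = 1e-6, max_iterations = 25L,
                    automation = c("fully_automated", "semi_automated",
                                   "manual"),
                    approval = NULL, n_bins = 20L, poll_interval = 0.5,
                    timeout = 300) {
  automation <- match.arg(automation)
  m <- read_manifest(root)
  layout <- folder_layout(root, m$n_partners)
  spec <- design_spec(m$family, m$covariates)
  gate <- approval_gate(automation, callback = approval)
  edges <- default_bin_edges(n_bins)
  partners <- lapply(seq_len(m$n_partners), function(k)
    partner_node(k, layout, spec, gate = gate, bin_edges = edges))
  center <- center_node(layout, spec, gate = gate, tolerance = tolerance,
                        max_iterations = max_iterations,
                        poll_interval = poll_interval, timeout = timeout,
                        bin_edges = edges)
  pump <- function() {
    for (nd in partners)
      if (!nd$terminated)
        partner_serve_once(nd, interval = min(poll_interval, 0.05),
                           timeout = timeout)
  }
  res <- tryCatch(run_center(center, pump = pump),
                  dra_approval_denied = function(e) e)
  if (inherits(res, "dra_approval_denied")) {
    log_line(layout$center$run_log, "center", "aborted", NA,
             conditionMessage(res))
    return(structure(list(fit = NULL, diagnostics = NULL, status = NULL,
                          n_broadcasts = center$n_broadcasts,
                          report_files = character(0), aborted = TRUE,
                          message = conditionMessage(res), exit_code = 2L,
                          layout = layout),
                     class = "dra_run_result"))
  }
  res$aborted <- FALSE
  res$exit_code <- if (isTRUE(res$fit$converged)) 0L else 1L
  res$layout <- layout
  class(res) <- "dra_run_result"
  res
}

#' Verify a finished (or aborted) run against the protocol contract
#'
#' Replays the audit log and checks the run's integrity: every archived
#' transferred file must pass the aggregate-only privacy audit
#' ([audit_payload()]), no monitored folder may retain a stale trigger
#' file, every deposit record must reference its archive, and the audit
#' log's broadcast count must agree with the run report.
#'
#' @param root Run root directory.
#' @return A `dra_verification` object; its `pass` field is `TRUE` only
#'   if every check passed.
#' @export
dra_verify <- function(root) {
  m <- read_manifest(root)
  layout <- folder_layout(root, m$n_partners)
  if (!file.exists(layout$center$audit_log))
    abort_config(sprintf("no audit log found under '%s'", root))
  log <- read_audit_log(layout$center$audit_log)

  checks <- list()
  add <- function(name, pass, detail)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)

  archived <- list.files(layout$center$archive, recursive = TRUE,
                         full.names = TRUE)
  if (length(archived)) {
    audit <- audit_payload(archived)
    nfail <- sum(!audit$pass)
    add("privacy_audit", nfail == 0L,
        sprintf("%d/%d archived transferred files aggregate-only",
                nrow(audit) - nfail, nrow(audit)))
  } else {
    add("privacy_audit", FALSE, "no archived transfers found")
    audit <- NULL
  }

  stale <- stale_triggers(root)
  add("trigger_lifecycle", length(stale) == 0L,
      if (length(stale)) sprintf("stale trigger(s): %s",
                                 paste(stale, collapse = ", "))
      else "no stale trigger files")

  transferred <- log[log$status == "transferred", ]
  missing_arch <- sum(!nzchar(transferred$archive))
  add("audit_completeness", missing_arch == 0L,
      sprintf("%d/%d deposit records archived",
              nrow(transferred) - missing_arch, nrow(transferred)))

  meta_path <- file.path(dirname(layout$center$audit_log), "run_meta.dcf")
  if (file.exists(meta_path)) {
    meta <- as.data.frame(read.dcf(meta_path), stringsAsFactors = FALSE)
    n_bc <- as.integer(meta$n_broadcasts)
    ctp <- transferred[transferred$direction == "center_to_partner", ]
    replayed <- length(unique(ctp$iteration))
    add("audit_replay", replayed == n_bc,
        sprintf("audit log replays %d broadcast iteration(s); report says %d",
                replayed, n_bc))
  }

  checks <- do.call(rbind, checks)
  structure(list(root = root, checks = checks, pass = all(checks$pass),
                 audit = audit, n_denied = sum(log$status == "denied")),
            class = "dra_verification")
}

#' @export
print.dra_verification <- function(x, ...) {
  cat(sprintf("Run verification for %s\n", x$root))
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  [%s] %s: %s\n",
                if (x$checks$pass[i]) "PASS" else "FAIL",
                x$checks$check[i], x$checks$detail[i]))
  cat(sprintf("overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
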