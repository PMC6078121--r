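TRIGGER_FILES <- c(files_done = "files_done.ok", job_done = "job_done.ok")

#' Name of the marker file for a trigger kind
#'
#' Two zero-length trigger files drive the whole protocol:
#' `files_done.ok` ("a payload is complete and ready for pickup") and
#' `job_done.ok` ("the analysis is finished; compute diagnostics and
#' shut down").  Trigger files carry no content — all semantics live in
#' the payload files they announce.
#'
#' @param kind `"files_done"` or `"job_done"`.
#' @return The marker file name.
#' @export
trigger_filename <- function(kind) {
  if (!kind %in% names(TRIGGER_FILES))
    abort_config(sprintf("unknown trigger kind '%s'", kind))
  unname(TRIGGER_FILES[kind])
}

#' The common folder structure shared by all nodes
#'
#' Each data partner has the four-folder site convention: `sasprogram`
#' (analysis programs), `inputfiles` (parameter files from the center),
#' `dplocal` (the patient-level analytic dataset, which never leaves the
#' site), and `msoc` (outbound aggregate results).  The center has its
#' own `inputfiles` plus one inbox per partner named `msoc1` ... `msocK`
#' (1-based partner index, assigned by sorted partner id).  Each node
#' additionally gets a private `work` folder into which consumed files
#' are moved — the consumer's workspace, never monitored.
#'
#' @param root Run root directory.
#' @param n_partners Number of data partners (>= 1).
#' @return A `dra_layout` object holding all paths.
#' @export
folder_layout <- function(root, n_partners) {
  n_partners <- as.integer(n_partners)
  if (is.na(n_partners) || n_partners < 1L)
    abort_config("n_partners must be >= 1")
  partners <- lapply(seq_len(n_partners), function(k) {
    base <- file.path(root, sprintf("partner%d", k))
    list(id = k,
         sasprogram = file.path(base, "sasprogram"),
         inputfiles = file.path(base, "inputfiles"),
         dplocal    = file.path(base, "dplocal"),
         msoc       = file.path(base, "msoc"),
         work       = file.path(base, "work"))
  })
  center_base <- file.path(root, "center")
  center <- list(
    inputfiles = file.path(center_base, "inputfiles"),
    inbox = vapply(seq_len(n_partners), function(k)
      file.path(center_base, sprintf("msoc%d", k)), ""),
    archive = file.path(center_base, "archive"),
    work = file.path(center_base, "work"),
    audit_log = file.path(center_base, "audit_log.csv"),
    run_log = file.path(center_base, "run_log.txt")
  )
  structure(list(root = root, n_partners = n_partners,
                 partners = partners, center = center),
            class = "dra_layout")
}

#' Create the folder tree for a layout
#' @param layout A [folder_layout()].
#' @return `layout`, invisibly.
#' @export
create_layout <- function(layout) {
  stopifnot(inherits(layout, "dra_layout"))
  dirs <- c(unlist(lapply(layout$partners, function(p)
              c(p$sasprogram, p$inputfiles, p$dplocal, p$msoc, p$work))),
            layout$center$inputfiles, layout$center$inbox,
            layout$center$archive, layout$center$work)
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  invisible(layout)
}

#' Approval gating for file transfers
#'
#' Three automation levels control when a human (here: a callback) must
#' approve a transfer: `manual` gates every deposit and every consume;
#' `semi_automated` gates only files leaving a partner's `msoc` folder
#' (the review partners care most about — what leaves their site);
#' `fully_automated` gates nothing.
#'
#' @param level Automation level.
#' @param callback `function(action, direction, partner_id, files)`
#'   returning `TRUE` (approve) or `FALSE` (deny).  Defaults to
#'   approve-all.
#' @param approver Label recorded in the audit log for approved
#'   transfers that went through the callback.
#' @return A `dra_gate` object.
#' @export
approval_gate <- function(level = c("fully_automated", "semi_automated", "manual"),
                          callback = NULL, approver = "callback") {
  level <- match.arg(level)
  if (is.null(callback)) callback <- function(action, direction, partner_id, files) TRUE
  structure(list(level = level, callback = callback, approver = approver),
            class = "dra_gate")
}

gate_check <- function(gate, action, direction, partner_id, files,
                       leaving_partner_msoc = FALSE) {
  needed <- switch(gate$level,
    fully_automated = FALSE,
    manual = TRUE,
    semi_automated = leaving_partner_msoc)
  if (!needed) return(list(approved = TRUE, approved_by = "auto"))
  ok <- isTRUE(gate$callback(action, direction, partner_id, files))
  list(approved = ok, approved_by = if (ok) gate$approver else "denied")
}

# write-to-temporary-name then rename within the same directory: a
# consumer keyed on the trigger can never observe a half-written payload
atomic_copy <- function(src, dest_dir) {
  dest <- file.path(dest_dir, basename(src))
  tmp <- file.path(dest_dir, paste0(".tmp.", basename(src)))
  if (!file.copy(src, tmp, overwrite = TRUE))
    abort_transfer(sprintf("failed to copy '%s' into '%s'", src, dest_dir))
  if (!file.rename(tmp, dest))
    abort_transfer(sprintf("failed to finalize '%s'", dest))
  dest
}

atomic_touch <- function(path) {
  tmp <- file.path(dirname(path), paste0(".tmp.", basename(path)))
  file.create(tmp)
  if (!file.rename(tmp, path))
    abort_transfer(sprintf("failed to create trigger '%s'", path))
  path
}

audit_log_append <- function(log_path, record) {
  new <- !file.exists(log_path)
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  utils::write.table(df, log_path, append = !new, col.names = new,
                     row.names = FALSE, sep = ",", qmethod = "double")
}

#' Read the append-only transfer audit log
#' @param log_path Path to the audit log CSV.
#' @return Data frame of transfer records.
#' @export
read_audit_log <- function(log_path) {
  if (!file.exists(log_path)) abort_config("audit log not found")
  utils::read.csv(log_path, stringsAsFactors = FALSE)
}

#' Deposit payload files and signal with a trigger
#'
#' Copies every payload file into `dest` (write-then-rename, so partial
#' files are never visible under their final name), archives a copy for
#' later audit when `archive_dir` is given, appends a transfer record to
#' the audit log, and only then creates the trigger marker.  The trigger
#' is therefore a guarantee that the payload is complete.
#'
#' A denied approval aborts the transfer before any payload byte lands
#' in `dest`; the denial itself is recorded in the audit log.
#'
#' @param files Paths of payload files to transfer.
#' @param dest Destination folder (must exist).
#' @param trigger `"files_done"` or `"job_done"`.
#' @param gate An [approval_gate()].
#' @param direction `"center_to_partner"` or `"partner_to_center"`.
#' @param partner_id Partner involved in the transfer.
#' @param iteration Protocol iteration index.
#' @param log_path Audit log file (optional).
#' @param archive_dir Folder receiving audit copies (optional).
#' @param leaving_partner_msoc `TRUE` when the files are leaving a
#'   partner's `msoc` folder (the semi-automated gate point).
#' @return The transfer record, invisibly.
#' @export
deposit <- function(files, dest, trigger, gate = approval_gate(),
                    direction = "center_to_partner", partner_id = NA_integer_,
                    iteration = NA_integer_, log_path = NULL,
                    archive_dir = NULL, leaving_partner_msoc = FALSE) {
  if (!dir.exists(dest))
    abort_config(sprintf("destination folder '%s' does not exist", dest))
  tname <- trigger_filename(trigger)
  ok <- gate_check(gate, "deposit", direction, partner_id, files,
                   leaving_partner_msoc)
  record <- list(timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
                 event = "deposit", direction = direction,
                 iteration = as.integer(iteration),
                 partner_id = as.integer(partner_id),
                 files = paste(basename(files), collapse = ";"),
                 bytes = sum(file.size(files)),
                 trigger = tname,
                 approved_by = ok$approved_by,
                 status = if (ok$approved) "transferred" else "denied",
                 archive = "")
  if (!ok$approved) {
    if (!is.null(log_path)) audit_log_append(log_path, record)
    dra_abort(sprintf("transfer to '%s' denied by approval gate", dest),
              "dra_approval_denied")
  }
  if (!is.null(archive_dir)) {
    dir.create(archive_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in files) file.copy(f, file.path(archive_dir, basename(f)),
                               overwrite = TRUE)
    record$archive <- archive_dir
  }
  for (f in files) atomic_copy(f, dest)
  if (!is.null(log_path)) audit_log_append(log_path, record)
  atomic_touch(file.path(dest, tname))
  invisible(record)
}

#' Poll a folder until a trigger file appears
#'
#' Emulates the folder-monitoring functionality: checks for the trigger
#' marker every `interval` seconds, returning `TRUE` as soon as it
#' exists and `FALSE` once `timeout` seconds have elapsed.  Never
#' consumes anything.
#'
#' @param folder Folder to watch.
#' @param trigger Trigger kind.
#' @param interval Poll interval in seconds (> 0).
#' @param timeout Give-up time in seconds.
#' @return Logical: was the trigger seen?
#' @export
poll_for_trigger <- function(folder, trigger, interval = 0.5, timeout = 300) {
  stopifnot_scalar_number(interval, "interval", positive = TRUE)
  if (!dir.exists(folder))
    abort_config(sprintf("monitored folder '%s' does not exist", folder))
  target <- file.path(folder, trigger_filename(trigger))
  deadline <- Sys.time() + timeout
  repeat {
    if (file.exists(target)) return(TRUE)
    if (Sys.time() >= deadline) return(FALSE)
    Sys.sleep(min(interval, as.numeric(difftime(deadline, Sys.time(),
                                                units = "secs"))))
  }
}

#' Consume a signalled payload
#'
#' Moves every payload file out of `folder` into the consumer's
#' `workspace` and deletes the trigger marker, so the appearance of a
#' new trigger in the next iteration starts a fresh transfer.  Moving
#' (not copying) prevents double processing; calling consume twice on
#' the same trigger is a protocol error.
#'
#' @param folder Folder holding payload + trigger.
#' @param trigger Trigger kind to consume.
#' @param workspace Folder receiving the payload files.
#' @param gate An [approval_gate()].
#' @param direction,partner_id Context for the approval callback.
#' @param leaving_partner_msoc `TRUE` when consuming from a partner's
#'   `msoc` folder.
#' @return Character vector of workspace paths of the payload files
#'   (possibly empty).
#' @export
consume <- function(folder, trigger, workspace, gate = approval_gate(),
                    direction = "partner_to_center",
                    partner_id = NA_integer_,
                    leaving_partner_msoc = FALSE) {
  tpath <- file.path(folder, trigger_filename(trigger))
  if (!file.exists(tpath))
    abort_protocol(sprintf("no '%s' trigger present in '%s'",
                           trigger_filename(trigger), folder))
  all_files <- list.files(folder, full.names = TRUE, all.files = FALSE)
  payload <- all_files[!basename(all_files) %in% TRIGGER_FILES &
                         !dir.exists(all_files)]
  ok <- gate_check(gate, "consume", direction, partner_id, payload,
                   leaving_partner_msoc)
  if (!ok$approved)
    dra_abort(sprintf("consume from '%s' denied by approval gate", folder),
              "dra_approval_denied")
  dir.create(workspace, recursive = TRUE, showWarnings = FALSE)
  moved <- character(0)
  for (f in payload) {
    to <- file.path(workspace, basename(f))
    if (!file.rename(f, to)) {        # cross-device fallback
      file.copy(f, to, overwrite = TRUE)
      file.remove(f)
    }
    moved <- c(moved, to)
  }
  file.remove(tpath)
  moved
}

#' List stale trigger files under a run root
#'
#' After a completed run no monitored folder may still contain a trigger
#' marker; any hit indicates a protocol-lifecycle violation.
#'
#' @param root Run root directory.
#' @return Character vector of paths of leftover trigger files.
#' @export
stale_triggers <- function(root) {
  hits <- list.files(root, recursive = TRUE, full.names = TRUE,
                     all.files = TRUE)
  hits[basename(hits) %in% TRIGGER_FILES]
}
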