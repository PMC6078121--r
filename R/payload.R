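#' Parameter state distributed by the analysis center
#'
#' The "guesses" of the regression parameters broadcast to every partner
#' at each iteration, plus the terminal `job_done` flag that tells
#' partners to compute diagnostics and shut down.
#'
#' @param beta Numeric parameter vector (finite).
#' @param iteration Positive iteration index; strictly increases across
#'   successive distributions within one run.
#' @param family Model family the run is fitting.
#' @param job_done Logical: `TRUE` only on the terminal broadcast.
#' @return A `dra_beta_state` payload.
#' @export
beta_state <- function(beta, iteration, family, job_done = FALSE) {
  beta <- as.numeric(beta)
  if (length(beta) && !all(is.finite(beta)))
    abort_config("beta contains non-finite entries")
  structure(list(kind = "beta_state", family = family,
                 iteration = as.integer(iteration), p = length(beta),
                 beta = beta, job_done = isTRUE(job_done)),
            class = c("dra_beta_state", "dra_payload"))
}

error_payload <- function(message, family, iteration, partner_id) {
  structure(list(kind = "error", family = family,
                 iteration = as.integer(iteration),
                 partner_id = as.integer(partner_id),
                 message = as.character(message)),
            class = c("dra_error_payload", "dra_payload"))
}

fmt17 <- function(x) sprintf("%.17g", as.numeric(x))

ut_index <- function(p) which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)

mat_lines <- function(name, m) {
  ut <- ut_index(nrow(m))
  sprintf("%s.%d.%d,%s", name, ut[, 1L], ut[, 2L], fmt17(m[ut]))
}

vec_lines <- function(name, v) {
  if (!length(v)) return(character(0))
  sprintf("%s.%d,%s", name, seq_along(v), fmt17(v))
}

mat_from_entries <- function(entries, name, p) {
  m <- matrix(0, p, p)
  ut <- ut_index(p)
  keys <- sprintf("%s.%d.%d", name, ut[, 1L], ut[, 2L])
  if (!all(keys %in% names(entries)))
    abort_parse(sprintf("payload section '%s' is incomplete", name))
  m[ut] <- as.numeric(entries[keys])
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

vec_from_entries <- function(entries, name, len) {
  if (len == 0L) return(numeric(0))
  keys <- sprintf("%s.%d", name, seq_len(len))
  if (!all(keys %in% names(entries)))
    abort_parse(sprintf("payload section '%s' is incomplete", name))
  as.numeric(entries[keys])
}

#' Write an intermediate-statistics or parameter payload file
#'
#' Payload files are the only artifacts that ever cross a site boundary,
#' so the format is deliberately transparent: plain UTF-8 text, one
#' `key,value` pair per line, with matrix sections stored as their upper
#' triangle.  Numeric values are written with 17 significant digits so a
#' write/read round trip reproduces IEEE doubles exactly, which keeps a
#' file-based run bit-identical to an in-memory one.
#'
#' @param payload A `dra_payload` object.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_payload <- function(payload, path) {
  stopifnot(inherits(payload, "dra_payload"))
  hdr <- c("format_version,1",
           sprintf("kind,%s", payload$kind),
           sprintf("family,%s", payload$family),
           sprintf("iteration,%d", payload$iteration))
  body <- switch(payload$kind,
    beta_state = c(sprintf("p,%d", payload$p),
                   sprintf("job_done,%d", as.integer(payload$job_done)),
                   vec_lines("beta", payload$beta)),
    linear_summaries = c(sprintf("partner_id,%d", payload$partner_id),
                         sprintf("p,%d", payload$p),
                         sprintf("n,%d", payload$n),
                         sprintf("yty,%s", fmt17(payload$yty)),
                         vec_lines("xty", payload$xty),
                         mat_lines("xtx", payload$xtx)),
    score_info = c(sprintf("partner_id,%d", payload$partner_id),
                   sprintf("p,%d", payload$p),
                   sprintf("n,%d", payload$n),
                   sprintf("n_events,%d", payload$n_events),
                   sprintf("loglik,%s", fmt17(payload$loglik)),
                   vec_lines("gradient", payload$gradient),
                   mat_lines("information", payload$information)),
    diagnostics = c(sprintf("partner_id,%d", payload$partner_id),
                    sprintf("p,%d", payload$p),
                    sprintf("n,%d", payload$n),
                    sprintf("n_events,%d", payload$n_events),
                    sprintf("loglik_final,%s", fmt17(payload$loglik_final)),
                    sprintf("n_bins,%d", payload$n_bins),
                    vec_lines("bin_edges", payload$bin_edges),
                    vec_lines("bin_n", payload$bin_n),
                    vec_lines("bin_sum_y", payload$bin_sum_y),
                    vec_lines("bin_sum_p", payload$bin_sum_p)),
    error = c(sprintf("partner_id,%d", payload$partner_id),
              sprintf("message,%s", gsub("[\r\n]+", " ", payload$message))),
    abort_config(sprintf("unknown payload kind '%s'", payload$kind))
  )
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a payload file written by [write_payload()]
#'
#' @param path Payload file path.
#' @return The reconstructed `dra_payload` object.
#' @export
read_payload <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("payload file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sep <- regexpr(",", lines, fixed = TRUE)
  if (any(sep < 0))
    abort_parse(sprintf("line %d of '%s' is not a key,value pair",
                        which(sep < 0)[1L], basename(path)))
  keys <- substr(lines, 1L, sep - 1L)
  vals <- substr(lines, sep + 1L, nchar(lines))
  if (anyDuplicated(keys))
    abort_parse(sprintf("duplicate key '%s' in '%s'",
                        keys[duplicated(keys)][1L], basename(path)))
  entries <- stats::setNames(vals, keys)
  need <- function(key) {
    if (!key %in% names(entries))
      abort_parse(sprintf("payload '%s' lacks required key '%s'",
                          basename(path), key))
    entries[[key]]
  }
  if (!identical(need("format_version"), "1"))
    abort_parse("unsupported payload format version")
  kind <- need("kind")
  family <- need("family")
  iteration <- as.integer(need("iteration"))
  switch(kind,
    beta_state = {
      p <- as.integer(need("p"))
      beta_state(vec_from_entries(entries, "beta", p), iteration, family,
                 job_done = as.integer(need("job_done")) == 1L)
    },
    linear_summaries = {
      p <- as.integer(need("p"))
      out <- list(kind = "linear_summaries", family = family,
                  iteration = iteration,
                  partner_id = as.integer(need("partner_id")),
                  p = p, n = as.integer(need("n")),
                  xtx = mat_from_entries(entries, "xtx", p),
                  xty = vec_from_entries(entries, "xty", p),
                  yty = as.numeric(need("yty")))
      class(out) <- c("dra_linear_summaries", "dra_payload")
      out
    },
    score_info = {
      p <- as.integer(need("p"))
      score_info(family,
                 n = as.integer(need("n")),
                 n_events = as.integer(need("n_events")),
                 gradient = vec_from_entries(entries, "gradient", p),
                 information = mat_from_entries(entries, "information", p),
                 loglik = as.numeric(need("loglik")),
                 iteration = iteration,
                 partner_id = as.integer(need("partner_id")))
    },
    diagnostics = {
      nb <- as.integer(need("n_bins"))
      new_diagnostics_payload(
        family = family, iteration = iteration,
        partner_id = as.integer(need("partner_id")),
        p = as.integer(need("p")), n = as.integer(need("n")),
        n_events = as.integer(need("n_events")),
        loglik_final = as.numeric(need("loglik_final")),
        bin_edges = vec_from_entries(entries, "bin_edges",
                                     if (nb > 0L) nb + 1L else 0L),
        bin_n = vec_from_entries(entries, "bin_n", nb),
        bin_sum_y = vec_from_entries(entries, "bin_sum_y", nb),
        bin_sum_p = vec_from_entries(entries, "bin_sum_p", nb))
    },
    error = error_payload(need("message"), family, iteration,
                          as.integer(need("partner_id"))),
    abort_parse(sprintf("unknown payload kind '%s' in '%s'", kind,
                        basename(path)))
  )
}

# expected key,value line count for each payload kind; a function of the
# parameter count p (and bin count) only -- never of the patient count n
payload_expected_lines <- function(kind, p, n_bins = 0L) {
  tri <- p * (p + 1L) / 2L
  4L + switch(kind,
    beta_state       = 2L + p,
    linear_summaries = 4L + p + tri,
    score_info       = 5L + p + tri,
    diagnostics      = 6L + (if (n_bins > 0L) n_bins + 1L else 0L) + 3L * n_bins,
    error            = 2L,
    abort_config(sprintf("unknown payload kind '%s'", kind)))
}

#' Audit transferred files for aggregate-only content
#'
#' The privacy contract of the protocol is that every transferred file's
#' numeric content has size determined by the number of model parameters
#' (plus, for diagnostics, the fixed bin count) — never by the number of
#' patients.  This audit re-parses each file and checks its line count
#' against the closed-form expectation for its kind; anything that fails
#' to parse, or whose size deviates, is flagged as a violation.
#'
#' @param files Character vector of payload file paths.
#' @return A data frame with one row per file: `file`, `kind`, `p`,
#'   `n_lines`, `expected_lines`, `pass`, `detail`; attribute
#'   `"verdict"` is `"pass"` only if every file passes.
#' @export
audit_payload <- function(files) {
  rows <- lapply(files, function(f) {
    n_lines <- length(readLines(f, warn = FALSE))
    pl <- tryCatch(read_payload(f), error = function(e) e)
    if (inherits(pl, "error")) {
      return(data.frame(file = basename(f), kind = NA_character_,
                        p = NA_integer_, n_lines = n_lines,
                        expected_lines = NA_integer_, pass = FALSE,
                        detail = paste("unparseable:", conditionMessage(pl)),
                        stringsAsFactors = FALSE))
    }
    nb <- if (pl$kind == "diagnostics") pl$n_bins else 0L
    exp_lines <- payload_expected_lines(pl$kind, pl$p, nb)
    ok <- n_lines == exp_lines
    data.frame(file = basename(f), kind = pl$kind, p = pl$p,
               n_lines = n_lines, expected_lines = exp_lines, pass = ok,
               detail = if (ok) "" else
                 "content size inconsistent with aggregate-only format",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "verdict") <- if (all(out$pass)) "pass" else "fail"
  out
}
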