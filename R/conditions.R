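# Classed conditions so callers can distinguish schema/data/protocol/estimation
# failures; every abort goes through here.

dra_abort <- function(message, class, call = sys.call(-1L)) {
  stop(structure(
    class = c(class, "dra_condition", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_schema     <- function(msg) dra_abort(msg, "dra_schema_error")
abort_data       <- function(msg) dra_abort(msg, "dra_data_error")
abort_config     <- function(msg) dra_abort(msg, "dra_config_error")
abort_protocol   <- function(msg) dra_abort(msg, "dra_protocol_error")
abort_estimation <- function(msg) dra_abort(msg, "dra_estimation_error")
abort_transfer   <- function(msg) dra_abort(msg, "dra_transfer_error")
abort_audit      <- function(msg) dra_abort(msg, "dra_audit_error")
abort_parse      <- function(msg) dra_abort(msg, "dra_parse_error")

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    abort_config(sprintf("'%s' must be > 0", name))
  invisible(x)
}
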