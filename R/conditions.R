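# Structured conditions: every parse/validation failure signals a condition of
# class c("csm_error_<what>", "csm_error", "error") so callers (and the CLI)
# can dispatch on the failure kind. `offset` is the 0-based character offset
# into the offending string, when known.

csm_abort <- function(msg, class, offset = NULL) {
  if (!is.null(offset)) {
    msg <- sprintf("%s (at offset %d)", msg, as.integer(offset))
  }
  cond <- errorCondition(
    msg,
    class  = c(paste0("csm_error_", class), "csm_error"),
    offset = offset
  )
  stop(cond)
}

csm_warn <- function(msg, class) {
  cond <- warningCondition(
    msg,
    class = c(paste0("csm_warning_", class), "csm_warning")
  )
  warning(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
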