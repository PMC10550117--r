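# Classed conditions so callers (and tests) can react to failure modes
# programmatically instead of matching message strings.

lf_abort <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(paste0("lucflow_", class, "_error"), "lucflow_error",
              "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

lf_contract <- function(msg, ...) lf_abort("contract", msg, ...)

lf_warn <- function(class, msg) {
  cond <- structure(
    class = c(paste0("lucflow_", class, "_warning"), "lucflow_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
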