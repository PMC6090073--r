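# Classed error conditions so callers (and the CLI's exit codes) can tell
# the two diagnosable failure modes apart from plain I/O or usage errors.
stop_cervroi <- function(class, message, stage = NULL) {
  if (!is.null(stage)) {
    message <- sprintf("%s [stage: %s]", message, stage)
  }
  cond <- structure(
    class = c(paste0("cervroi_", class), "error", "condition"),
    list(message = message, call = NULL)
  )
  stop(cond)
}
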