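# Classed conditions so callers (and the CLI) can distinguish domain errors.
kfc_error <- function(msg, class) {
  stop(structure(
    class = c(class, "kfc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

kfc_warning <- function(msg, class) {
  warning(structure(
    class = c(class, "kfc_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
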