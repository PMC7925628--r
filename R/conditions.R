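# Classed conditions so callers can branch on failure modes rather than
# matching message text. Every error carries class c(<specific>, "ddi_error").

ddi_error <- function(class, message, ..., call. = FALSE) {
  stop(errorCondition(message, ..., class = c(class, "ddi_error")))
}

ddi_warning <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "ddi_warning")))
}
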