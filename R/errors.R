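# Classed conditions so the CLI can map validation errors to exit code 2
# and everything else to exit code 1.

ob_stop <- function(msg, class = "ob_input_error") {
  stop(structure(
    class = c(class, "ob_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

ob_config_stop <- function(msg) ob_stop(msg, class = "ob_config_error")

ob_assert <- function(cond, msg) {
  if (!isTRUE(cond)) ob_stop(msg)
  invisible(TRUE)
}
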