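# Classed conditions so callers (and the CLI) can map failures to exit codes:
# format errors -> 2, parameter errors -> 3, degenerate statistics -> 4.

abort_format <- function(msg, ...) {
  stop(structure(
    class = c("laci_format_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_parameter <- function(msg, ...) {
  stop(structure(
    class = c("laci_parameter_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_degenerate <- function(msg, ...) {
  stop(structure(
    class = c("laci_degenerate_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
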