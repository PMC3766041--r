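## Classed conditions so callers (and the command-line driver) can map
## failure modes to distinct exit codes without matching message text.

mrfStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("mrflow_", class), "mrflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

mrfWarn <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(
    class = c(paste0("mrflow_", class), "mrflow_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## shorthands for the recurring failure modes
stopArgument <- function(fmt, ...) mrfStop("argument_error", fmt, ...)
stopRange    <- function(fmt, ...) mrfStop("range_error", fmt, ...)
stopConfig   <- function(fmt, ...) mrfStop("config_error", fmt, ...)
stopGeometry <- function(fmt, ...) mrfStop("geometry_error", fmt, ...)
stopParse    <- function(fmt, ...) mrfStop("parse_error", fmt, ...)
stopMissing  <- function(fmt, ...) mrfStop("missing_data_error", fmt, ...)
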