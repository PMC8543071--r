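# Classed error conditions used across the package. Every domain error is a
# subclass of "wm_error" so callers can distinguish pipeline failures from
# programming errors.

abort_wm <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "wm_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# convenience wrappers; class names mirror the contract vocabulary
stop_invalid_input      <- function(msg) abort_wm(msg, "wm_invalid_input")
stop_configuration      <- function(msg) abort_wm(msg, "wm_configuration_error")
stop_parse              <- function(msg) abort_wm(msg, "wm_parse_error")
stop_schema             <- function(msg) abort_wm(msg, "wm_schema_error")
stop_missing_response   <- function(msg) abort_wm(msg, "wm_missing_response")
stop_incomplete_design  <- function(msg) abort_wm(msg, "wm_incomplete_design")
stop_insufficient_data  <- function(msg) abort_wm(msg, "wm_insufficient_data")
stop_degenerate         <- function(msg) abort_wm(msg, "wm_degenerate_variance")
stop_io                 <- function(msg) abort_wm(msg, "wm_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
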