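# Classed conditions so callers (and the engine) can catch specific failures
# without string-matching messages.

stop_citesnow <- function(class, message, ...) {
  stop(structure(class = c(paste0("citesnow_", class), "citesnow_error",
                           "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

is_citesnow_error <- function(e, class) {
  inherits(e, paste0("citesnow_", class))
}
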