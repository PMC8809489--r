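# internal condition helpers: every user-facing error carries a subclass so
# callers can distinguish format/symmetry/element/... failures programmatically

ps_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "polyscape_error", "error")))
}

ps_format_error <- function(msg) ps_stop(msg, "polyscape_format_error")
ps_symmetry_error <- function(msg) ps_stop(msg, "polyscape_symmetry_error")
ps_element_error <- function(msg) ps_stop(msg, "polyscape_element_error")
ps_connectivity_error <- function(msg) ps_stop(msg, "polyscape_connectivity_error")
ps_value_error <- function(msg) ps_stop(msg, "polyscape_value_error")
ps_state_error <- function(msg) ps_stop(msg, "polyscape_state_error")
ps_coverage_error <- function(msg) ps_stop(msg, "polyscape_coverage_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
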