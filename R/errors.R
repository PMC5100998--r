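# Classed conditions so callers can dispatch on failure mode rather than
# matching message text.
stop_teckin <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "teckin_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
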