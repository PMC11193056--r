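# Internal condition helpers: classed errors so callers can distinguish
# validation failures from numerical ones.
stopc <- function(class, fmt, ...) {
  stop(structure(class = c(class, "mifGate_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
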