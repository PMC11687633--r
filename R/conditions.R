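# Structured condition classes so callers (and the CLI) can distinguish
# user-input problems from model-domain failures.

ts_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "ts_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_validation <- function(msg, ...) ts_stop("ts_validation_error", msg, ...)
stop_range      <- function(msg, ...) ts_stop("ts_range_error", msg, ...)
stop_domain     <- function(msg, ...) ts_stop("ts_domain_error", msg, ...)
stop_parse      <- function(msg, ...) ts_stop("ts_parse_error", msg, ...)
stop_model      <- function(msg, ...) ts_stop("ts_model_error", msg, ...)
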