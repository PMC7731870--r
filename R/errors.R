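# Classed conditions so callers and tests can distinguish failure modes.
# All inherit from "csqca_error".

stop_csqca <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "csqca_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

stop_schema <- function(msg, ...) stop_csqca(msg, "csqca_schema_error", ...)
stop_rate <- function(msg, ...) stop_csqca(msg, "csqca_rate_error", ...)
stop_degenerate <- function(msg, ...) stop_csqca(msg, "csqca_degenerate_error", ...)
stop_undefined <- function(msg, ...) stop_csqca(msg, "csqca_undefined_metric_error", ...)
stop_no_model <- function(msg, ...) stop_csqca(msg, "csqca_no_model_error", ...)
stop_spec <- function(msg, ...) stop_csqca(msg, "csqca_spec_error", ...)
stop_usage <- function(msg, ...) stop_csqca(msg, "csqca_usage_error", ...)

# comparisons against threshold fractions tolerate floating-point drift
EPS <- 1e-9
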