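# Classed error helpers used across the package so callers (and tests) can
# distinguish bad values, missing data, schema problems and short traces.

ricotem_abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ricotem_error", "error", "condition")))
}

abort_invalid_input <- function(msg) ricotem_abort(msg, "ricotem_invalid_input")
abort_invalid_parameter <- function(msg) ricotem_abort(msg, "ricotem_invalid_parameter")
abort_missing_data <- function(msg) ricotem_abort(msg, "ricotem_missing_data")
abort_insufficient_span <- function(msg) ricotem_abort(msg, "ricotem_insufficient_span")
abort_schema <- function(msg) ricotem_abort(msg, "ricotem_schema_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
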