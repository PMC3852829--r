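#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can distinguish bad files from bad data.

stop_parse <- function(msg, ..., call. = FALSE) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tfimpact_parse_error", "tfimpact_error")))
}

stop_validation <- function(msg, ..., call. = FALSE) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tfimpact_validation_error", "tfimpact_error")))
}

stop_domain <- function(msg, ..., call. = FALSE) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tfimpact_domain_error", "tfimpact_error")))
}

stop_config <- function(msg, ..., call. = FALSE) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tfimpact_config_error", "tfimpact_error")))
}
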