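# Internal helpers shared across modules.

# Round half-up (reports and fuzzy scores use a fixed 0.5-goes-up rule so
# results do not depend on IEEE round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

abort_schema <- function(msg) {
  rlang::abort(msg, class = c("nutrilink_schema_error", "nutrilink_error"))
}

abort_integrity <- function(msg) {
  rlang::abort(msg, class = c("nutrilink_integrity_error", "nutrilink_error"))
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = c("nutrilink_validation_error", "nutrilink_error"))
}

abort_config <- function(msg) {
  rlang::abort(msg, class = c("nutrilink_config_error", "nutrilink_error"))
}

abort_domain <- function(msg) {
  rlang::abort(msg, class = c("nutrilink_domain_error", "nutrilink_error"))
}

abort_usage <- function(msg) {
  rlang::abort(msg, class = c("nutrilink_usage_error", "nutrilink_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
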