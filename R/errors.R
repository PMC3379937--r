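# Classed conditions so callers can distinguish bad physics (domain), bad
# bookkeeping (validation/lookup), bad files (parse) and bad simulator
# settings (config). All inherit from "esadose_error".

esa_condition <- function(msg, class, call = sys.call(-2)) {
  structure(
    class = c(class, "esadose_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

domain_error <- function(msg) stop(esa_condition(msg, "esadose_domain_error"))
validation_error <- function(msg) stop(esa_condition(msg, "esadose_validation_error"))
lookup_error <- function(msg) stop(esa_condition(msg, "esadose_lookup_error"))
parse_error <- function(msg) stop(esa_condition(msg, "esadose_parse_error"))
config_error <- function(msg) stop(esa_condition(msg, "esadose_config_error"))
missing_data_error <- function(msg) stop(esa_condition(msg, "esadose_missing_data_error"))

check_scalar <- function(x, name, positive = TRUE, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    domain_error(sprintf("%s must be a single finite number", name))
  if (positive && !allow_zero && x <= 0)
    domain_error(sprintf("%s must be > 0 (got %g)", name, x))
  if (positive && allow_zero && x < 0)
    domain_error(sprintf("%s must be >= 0 (got %g)", name, x))
  invisible(x)
}

check_count <- function(x, name, minimum = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      abs(x - round(x)) > 1e-8)
    domain_error(sprintf("%s must be a single whole number", name))
  if (x < minimum)
    domain_error(sprintf("%s must be >= %d (got %g)", name, minimum, x))
  invisible(as.integer(round(x)))
}

# Half-up rounding (round(0.5) in base R goes to even); layer counts printed
# in the field round 10.33 -> 10 and 82.35 -> 82, with exact halves up.
round_half_up <- function(x) floor(x + 0.5)
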