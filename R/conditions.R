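#' @keywords internal
"_PACKAGE"

# Structured conditions used across the package.  Every user-facing failure
# falls into one of a small set of classes so that callers (and the CLI,
# which maps them to exit codes) can react programmatically:
#   ht_not_found_error   -- a queried identifier does not exist
#   ht_integrity_error   -- a dangling cross-reference between tables
#   ht_domain_error      -- a numeric argument outside its documented range
#   ht_config_error      -- an infeasible configuration
#   ht_parse_error       -- malformed input (file or structure string)
ht_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "ht_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

ht_warn <- function(message, class = "ht_warning") {
  warning(structure(
    class = c(class, "ht_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# scalar type checks ---------------------------------------------------------

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    ht_abort(sprintf("`%s` must be a single non-empty string", what),
             "ht_domain_error")
  }
  invisible(x)
}

assert_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    ht_abort(sprintf("`%s` must be a single integer >= %d", what, min),
             "ht_domain_error")
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    ht_abort(sprintf("`%s` must be a single number in [0, 1]", what),
             "ht_domain_error")
  }
  invisible(as.numeric(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
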