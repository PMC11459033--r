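`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "immunocompare_error")))
}

format_error <- function(msg) abort(msg, "immunocompare_format_error")
validation_error <- function(msg) abort(msg, "immunocompare_validation_error")

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    validation_error(sprintf("`%s` must be a single non-missing number", name))
  if (positive && x <= 0)
    validation_error(sprintf("`%s` must be strictly positive", name))
  invisible(x)
}

assert_fraction <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1)
    validation_error(sprintf("`%s` must lie in [0, 1]", name))
  invisible(x)
}

# lexicographic, locale-independent ordering used for deterministic tie-breaks
order_c_locale <- function(...) order(..., method = "radix")

log_note <- function(fmt, ...) message(sprintf(fmt, ...))
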