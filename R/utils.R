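# Internal validation helpers. All user-facing validation errors name the
# offending field so config problems are actionable from the command line.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, min = -Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (x < min) stop_field(field, sprintf("must be >= %s", min))
  if (integer && x != round(x)) stop_field(field, "must be an integer")
  invisible(x)
}

check_string <- function(x, field) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop_field(field, "must be a non-empty string")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
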