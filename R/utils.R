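# classed error helpers so callers can condition on failure mode
abort_vmhrv <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "vmhrv_error"), ...)
}

abort_insufficient <- function(message, ...) {
  abort_vmhrv(message, "vmhrv_error_insufficient_data", ...)
}

abort_argument <- function(message, ...) {
  abort_vmhrv(message, "vmhrv_error_argument", ...)
}

abort_parse <- function(message, ...) {
  abort_vmhrv(message, "vmhrv_error_parse", ...)
}

abort_validation <- function(message, ...) {
  abort_vmhrv(message, "vmhrv_error_validation", ...)
}

abort_undefined_metric <- function(message, ...) {
  abort_vmhrv(message, "vmhrv_error_undefined_metric", ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         inclusive = c(TRUE, TRUE)) {
  if (!is_scalar_number(x)) {
    abort_argument(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (inclusive[1]) x >= min else x > min
  hi_ok <- if (inclusive[2]) x <= max else x < max
  if (!lo_ok || !hi_ok) {
    abort_argument(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x,
      if (inclusive[1]) "[" else "(", min, max,
      if (inclusive[2]) "]" else ")"
    ))
  }
  invisible(x)
}

# running median with odd window, edges shrunk symmetrically
running_median <- function(x, k = 11L) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- k %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::median(x[lo:hi])
  }, numeric(1))
}
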