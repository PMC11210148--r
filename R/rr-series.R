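#' Construct an R-R interval series
#'
#' An `rr_series` is the atomic signal object of the package: an ordered
#' sequence of inter-beat (R-R) intervals in milliseconds together with the
#' cumulative beat times in seconds. It is stored as a tibble with columns
#' `beat` (index), `rr_ms` (interval ending at that beat) and `t_s` (time of
#' the terminating R peak, `cumsum(rr_ms) / 1000`), so it pipes directly into
#' dplyr/ggplot2 workflows.
#'
#' @param intervals Numeric vector of inter-beat intervals in milliseconds;
#'   all values must be strictly positive.
#' @param meta Named list of free-form labels (subject, condition,
#'   timepoint, ...) carried along as an attribute.
#'
#' @return A tibble of class `rr_series` with columns `beat`, `rr_ms`, `t_s`.
#' @examples
#' s <- rr_series(c(800, 810, 790))
#' rr_duration(s) # 2.4 seconds
#' @export
rr_series <- function(intervals, meta = list()) {
  if (length(intervals) == 0L) {
    out <- tibble::tibble(beat = integer(), rr_ms = numeric(), t_s = numeric())
    return(new_rr_series(out, meta))
  }
  if (!is.numeric(intervals)) {
    abort_validation("R-R intervals must be numeric.")
  }
  if (anyNA(intervals)) {
    abort_validation("R-R intervals must not contain missing values.")
  }
  if (any(intervals <= 0)) {
    bad <- which(intervals <= 0)[1]
    abort_validation(sprintf(
      "R-R intervals must be strictly positive; interval %d is %g ms.",
      bad, intervals[bad]
    ))
  }
  out <- tibble::tibble(
    beat = seq_along(intervals),
    rr_ms = as.numeric(intervals),
    t_s = cumsum(as.numeric(intervals)) / 1000
  )
  new_rr_series(out, meta)
}

new_rr_series <- function(data, meta = list()) {
  structure(
    data,
    meta = meta,
    class = c("rr_series", class(tibble::tibble()))
  )
}

#' @export
print.rr_series <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf(
    "<rr_series: %d beats, %.1f s, mean RR %.1f ms>\n",
    nrow(x), rr_duration(x), if (nrow(x)) mean(x$rr_ms) else NA_real_
  ))
  if (length(meta)) {
    cat("meta:", paste(names(meta), unlist(meta), sep = "=", collapse = ", "),
        "\n")
  }
  NextMethod()
}

#' Coerce to an R-R series
#'
#' @param x A numeric vector of intervals (ms), a data frame with an `rr_ms`
#'   column, or an existing `rr_series`.
#' @param ... Passed on to methods.
#' @return An [rr_series()].
#' @export
as_rr_series <- function(x, ...) UseMethod("as_rr_series")

#' @export
as_rr_series.rr_series <- function(x, ...) x

#' @export
as_rr_series.numeric <- function(x, ...) rr_series(x, ...)

#' @export
as_rr_series.data.frame <- function(x, ...) {
  if (!"rr_ms" %in% names(x)) {
    abort_argument("Data frame input needs an `rr_ms` column.")
  }
  rr_series(x$rr_ms, ...)
}

#' Total duration of an R-R series
#'
#' @param series An [rr_series()].
#' @return Duration in seconds (`sum(rr_ms) / 1000`).
#' @export
rr_duration <- function(series) {
  series <- as_rr_series(series)
  if (nrow(series) == 0L) return(0)
  series$t_s[nrow(series)]
}

rr_meta <- function(series) attr(series, "meta") %||% list()

#' Select the trailing window of a recording
#'
#' Returns the minimal suffix of beats whose cumulative span covers
#' `duration_s` seconds. The window is allowed to overshoot by less than one
#' interval (the boundary-covering beat is included) so that never less data
#' than prescribed is analyzed; on-task trials are conventionally scored from
#' their final 60 s.
#'
#' @param series An [rr_series()].
#' @param duration_s Window length in seconds (default 60).
#' @return An [rr_series()] spanning at least `duration_s` (within one beat).
#' @examples
#' s <- rr_series(rep(1000, 120))
#' nrow(segment_last(s, 60)) # 60 beats
#' @export
segment_last <- function(series, duration_s = 60) {
  series <- as_rr_series(series)
  check_number(duration_s, "duration_s", min = 0, inclusive = c(FALSE, TRUE))
  total <- rr_duration(series)
  if (total < duration_s) {
    abort_insufficient(
      sprintf("Recording spans %.1f s but a %.1f s window was requested.",
              total, duration_s),
      available_s = total, requested_s = duration_s
    )
  }
  span_from_end <- rev(cumsum(rev(series$rr_ms))) / 1000
  keep <- which(span_from_end <= duration_s)
  # include one earlier beat unless the kept suffix already covers the window
  first_keep <- if (length(keep)) keep[1] else nrow(series) + 1L
  if (first_keep > 1L && span_from_end[first_keep] < duration_s ||
      length(keep) == 0L) {
    first_keep <- first_keep - 1L
  }
  rr_series(series$rr_ms[first_keep:nrow(series)], meta = rr_meta(series))
}

#' Cut a time window out of a recording
#'
#' A beat belongs to the window if its *ending* time (the terminating R peak)
#' falls in the half-open interval `(t0, t1]`; this is the tachogram
#' convention, under which adjacent windows partition a recording exactly.
#' Resting segments are conventionally scored over a full 5-min window placed
#' after the acclimatization period.
#'
#' @param series An [rr_series()].
#' @param t0,t1 Window bounds in seconds, `0 <= t0 < t1`.
#' @return An [rr_series()] with the beats ending in `(t0, t1]`.
#' @examples
#' s <- rr_series(rep(1000, 300))
#' nrow(segment_window(s, 60, 120)) # 60 beats
#' @export
segment_window <- function(series, t0, t1) {
  series <- as_rr_series(series)
  check_number(t0, "t0", min = 0)
  check_number(t1, "t1", min = 0)
  if (t0 >= t1) {
    abort_argument(sprintf("Window bounds are inverted: t0 = %g >= t1 = %g.",
                           t0, t1))
  }
  keep <- series$t_s > t0 & series$t_s <= t1 + 1e-9
  rr_series(series$rr_ms[keep], meta = rr_meta(series))
}
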