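#' Read an R-R interval text file
#'
#' Reads the plain-text dialect exported by common wearable heart-rate
#' monitors: one interval per line, `#` starting a comment line, blank lines
#' ignored. Values are converted to milliseconds regardless of the unit on
#' disk.
#'
#' @param path Path to the file.
#' @param unit Unit of the stored values: `"ms"` (default) or `"s"`.
#' @param meta Optional named list attached to the resulting series.
#' @return An [rr_series()] in milliseconds.
#' @export
read_rr_text <- function(path, unit = c("ms", "s"), meta = list()) {
  unit <- match.arg(unit)
  if (!file.exists(path)) {
    abort_argument(sprintf("File not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  idx <- which(body)
  vals <- suppressWarnings(as.numeric(trimws(lines[body])))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1]]
    abort_parse(sprintf("Non-numeric token on line %d of %s: '%s'",
                        bad, path, trimws(lines[bad])))
  }
  if (unit == "s") vals <- vals * 1000
  if (any(vals <= 0)) {
    bad <- idx[which(vals <= 0)[1]]
    abort_validation(sprintf(
      "Non-positive R-R interval on line %d of %s.", bad, path))
  }
  rr_series(vals, meta = meta)
}

#' Write an R-R interval series as plain text
#'
#' One value (ms) per line after a single `#` header comment; integer
#' millisecond data round-trips bit-exactly through [read_rr_text()], and
#' fractional values are written without rounding.
#'
#' @param series An [rr_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr_text <- function(series, path) {
  series <- as_rr_series(series)
  lines <- c(
    "# R-R intervals [ms], one per line",
    vapply(series$rr_ms, function(v) sprintf("%.17g", v), character(1))
  )
  tryCatch(
    writeLines(lines, path),
    error = function(e) {
      abort_vmhrv(sprintf("Cannot write R-R file '%s': %s",
                          path, conditionMessage(e)), "vmhrv_error_io")
    }
  )
  invisible(path)
}

#' Read a timestamped R-R CSV export
#'
#' Accepts the two-column dialect `time_s, rr_ms` written by some logging
#' apps; only `rr_ms` defines the series (times are recomputed from the
#' cumulative sum so the invariants hold).
#'
#' @inheritParams read_rr_text
#' @return An [rr_series()].
#' @export
read_rr_csv <- function(path, meta = list()) {
  if (!file.exists(path)) {
    abort_argument(sprintf("File not found: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "rr_ms") %in% names(df))) {
    abort_parse(sprintf("%s must have columns time_s, rr_ms.", path))
  }
  rr_series(df$rr_ms, meta = meta)
}

session_tlx_cols <- c("tlx_effort", "tlx_mental", "tlx_temporal",
                      "tlx_physical", "tlx_performance", "tlx_frustration")

session_metric_cols <- c("mrr_ms", "mean_hr_bpm", "rmssd_ms", "hf_ms2",
                         "hf_nu", "sd1_ms", "pns_index")

session_key_cols <- c("subject_id", "phase", "game", "level", "timepoint")

#' Read / write a session table
#'
#' The session table is the long-format bookkeeping object of a study: one
#' row per `subject x phase x game x level x timepoint` with the vm-HRV
#' metric columns, the six raw NASA-TLX subscores (0-20) and a
#' `quality_pass` flag. Missing recordings stay as explicit `NA` rows and
#' are excluded (never imputed) downstream.
#'
#' @param path CSV path.
#' @return A tibble with the session-table columns.
#' @export
read_session_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_session_table(df)
}

#' @rdname read_session_table
#' @param sessions A session-table tibble.
#' @export
write_session_table <- function(sessions, path) {
  sessions <- validate_session_table(sessions)
  readr::write_csv(sessions, path, progress = FALSE)
  invisible(path)
}

validate_session_table <- function(df) {
  missing_keys <- setdiff(session_key_cols, names(df))
  if (length(missing_keys)) {
    abort_validation(paste0("Session table lacks key columns: ",
                            paste(missing_keys, collapse = ", ")))
  }
  if (anyDuplicated(df[session_key_cols])) {
    abort_validation(
      "Session table keys (subject, phase, game, level, timepoint) must be unique.")
  }
  if (!"quality_pass" %in% names(df)) df$quality_pass <- NA
  tibble::as_tibble(df)
}

#' Demand levels entering the reliability and validity analysis
#'
#' The adaptive familiarization level is excluded; only the three
#' standardized demand levels are analyzed.
#' @return Character vector `c("easy", "challenging", "excessive")`.
#' @export
analysis_levels <- function() c("easy", "challenging", "excessive")
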