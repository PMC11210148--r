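#' Age-predicted maximal heart rate
#'
#' Uses the regression `HRmax = 208 - 0.7 * age`. Ages are accepted as
#' reals; the formula is continuous.
#'
#' @param age Age in years, in `(0, 120)`.
#' @return Predicted maximal heart rate in bpm.
#' @examples
#' age_predicted_hrmax(60) # 166
#' @export
age_predicted_hrmax <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)) ||
      any(age <= 0) || any(age >= 120)) {
    abort_argument("`age` must be in (0, 120) years.")
  }
  208 - 0.7 * age
}

#' Karvonen heart-rate target
#'
#' Prescribes exercise intensity as a fraction of the heart-rate reserve
#' (HRR = HRmax - HRrest) above rest:
#' `HRtarget = (HRmax - HRrest) * fraction + HRrest`. The default fraction
#' 0.40 is the lower bound of the moderate-intensity band (40-59% HRR).
#'
#' @param hr_rest Resting heart rate (bpm).
#' @param hr_max Maximal heart rate (bpm), measured or from
#'   [age_predicted_hrmax()].
#' @param target_fraction Fraction of HRR, in `[0, 1]` (default 0.40).
#' @return Target heart rate in bpm.
#' @examples
#' karvonen_target(60, age_predicted_hrmax(67)) # 100.44
#' @export
karvonen_target <- function(hr_rest, hr_max, target_fraction = 0.40) {
  check_number(hr_rest, "hr_rest", min = 0, inclusive = c(FALSE, TRUE))
  check_number(hr_max, "hr_max", min = 0, inclusive = c(FALSE, TRUE))
  check_number(target_fraction, "target_fraction", min = 0, max = 1)
  if (hr_rest >= hr_max) {
    abort_argument("`hr_rest` must be below `hr_max`.")
  }
  (hr_max - hr_rest) * target_fraction + hr_rest
}

#' Ramp-test configuration
#'
#' Stepping-cadence ramp: start at 80 steps/min and increase by 5 steps/min
#' every 20 s until the target heart rate is reached.
#'
#' @param start_spm Starting cadence (steps/min).
#' @param increment_spm Cadence increment per stage.
#' @param stage_s Stage duration in seconds.
#' @return A `ramp_config` list.
#' @export
ramp_config <- function(start_spm = 80, increment_spm = 5, stage_s = 20) {
  for (nm in c("start_spm", "increment_spm", "stage_s")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) {
      abort_argument(sprintf("`%s` must be a positive number.", nm))
    }
  }
  structure(list(start_spm = start_spm, increment_spm = increment_spm,
                 stage_s = stage_s), class = "ramp_config")
}

#' Minimal stepping cadence reaching a target heart rate
#'
#' Walks the ramp stages over a sampled heart-rate stream, averages HR over
#' each stage window, and returns the cadence of the first stage whose
#' average meets or exceeds the target. The result is always on the cadence
#' grid `start + k * increment`.
#'
#' @param hr_stream A data frame with columns `time_s` and `hr_bpm` (samples
#'   of the live heart rate from the start of the ramp).
#' @param hr_target Target heart rate (bpm), e.g. from [karvonen_target()].
#' @param cfg A [ramp_config()].
#' @return Cadence in steps/min.
#' @export
ramp_test <- function(hr_stream, hr_target, cfg = ramp_config()) {
  stopifnot(inherits(cfg, "ramp_config"))
  if (!is.data.frame(hr_stream) ||
      !all(c("time_s", "hr_bpm") %in% names(hr_stream))) {
    abort_argument("`hr_stream` needs columns time_s and hr_bpm.")
  }
  check_number(hr_target, "hr_target", min = 0, inclusive = c(FALSE, TRUE))
  t_max <- max(hr_stream$time_s)
  if (t_max < cfg$stage_s) {
    abort_insufficient("HR stream does not cover a full ramp stage.")
  }
  n_stages <- ceiling(t_max / cfg$stage_s)
  last_spm <- NA_real_
  for (k in seq_len(n_stages) - 1L) {
    lo <- k * cfg$stage_s
    hi <- (k + 1L) * cfg$stage_s
    in_stage <- hr_stream$time_s >= lo & hr_stream$time_s < hi
    if (!any(in_stage)) next
    spm <- cfg$start_spm + k * cfg$increment_spm
    last_spm <- spm
    if (mean(hr_stream$hr_bpm[in_stage]) >= hr_target) {
      return(spm)
    }
  }
  abort_vmhrv(
    sprintf("Target HR %.1f bpm not reached within the stream (last stage %g steps/min).",
            hr_target, last_spm),
    "vmhrv_error_not_reached", last_stage_spm = last_spm
  )
}

#' Simulate a heart-rate stream for ramp testing
#'
#' Linear HR rise over the ramp with optional Gaussian sampling noise; a
#' desk-scale stand-in for a live monitor.
#'
#' @param hr_start Starting heart rate (bpm).
#' @param rise_bpm_per_stage HR increase per 20-s stage.
#' @param n_stages Number of stages to simulate.
#' @param fs Sampling rate in Hz.
#' @param noise_sd Sampling noise SD (bpm).
#' @param cfg A [ramp_config()].
#' @param seed Optional RNG seed for reproducibility.
#' @return A tibble with `time_s`, `hr_bpm`.
#' @export
simulate_hr_ramp <- function(hr_start = 70, rise_bpm_per_stage = 3,
                             n_stages = 20, fs = 1, noise_sd = 1,
                             cfg = ramp_config(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  t <- seq(0, n_stages * cfg$stage_s - 1 / fs, by = 1 / fs)
  hr <- hr_start + rise_bpm_per_stage * (t / cfg$stage_s) +
    stats::rnorm(length(t), 0, noise_sd)
  tibble::tibble(time_s = t, hr_bpm = hr)
}

#' Resting heart-rate stability check
#'
#' Session-to-session comparability rule: the current resting HR must stay
#' within an inclusive +/- `tol` bpm band around the baseline value.
#'
#' @param current_rest,baseline_rest Resting heart rates (bpm).
#' @param tol Band half-width in bpm (default 5, inclusive).
#' @return `TRUE` when within the band.
#' @examples
#' hr_rest_stable(65, 60) # TRUE (boundary is inclusive)
#' @export
hr_rest_stable <- function(current_rest, baseline_rest, tol = 5) {
  check_number(current_rest, "current_rest", min = 0, inclusive = c(FALSE, TRUE))
  check_number(baseline_rest, "baseline_rest", min = 0, inclusive = c(FALSE, TRUE))
  check_number(tol, "tol", min = 0)
  abs(current_rest - baseline_rest) <= tol
}

#' Raw NASA-TLX score
#'
#' The unweighted sum of the six 0-20 workload subscales (effort, mental,
#' temporal, physical, performance, frustration), giving a 0-120 total.
#' Accepts either six separate (vectorized) subscores or a data frame with
#' the `tlx_*` columns of a session table.
#'
#' @param effort A data frame carrying the six `tlx_*` columns, or the
#'   effort subscore vector.
#' @param mental,temporal,physical,performance,frustration Remaining
#'   subscores when given as vectors.
#' @return Numeric vector of raw TLX totals.
#' @examples
#' rtlx(5, 10, 3, 7, 2, 4) # 31
#' @export
rtlx <- function(effort, mental = NULL, temporal = NULL, physical = NULL,
                 performance = NULL, frustration = NULL) {
  if (is.data.frame(effort)) {
    df <- effort
    missing_cols <- setdiff(session_tlx_cols, names(df))
    if (length(missing_cols)) {
      abort_argument(paste0("Missing TLX columns: ",
                            paste(missing_cols, collapse = ", ")))
    }
    m <- as.matrix(df[session_tlx_cols])
  } else {
    m <- cbind(effort, mental, temporal, physical, performance, frustration)
  }
  if (any(!is.na(m) & (m < 0 | m > 20))) {
    abort_validation("TLX subscores must lie in [0, 20].")
  }
  out <- rowSums(m)
  unname(out)
}

#' Rest-to-task vm-HRV reactivity
#'
#' Absolute change of each metric from the resting to the on-task
#' recording: `on_task - rest`, per metric. Missing components propagate as
#' missing deltas.
#'
#' @param on_task,rest Metric tibbles as returned by [compute_hrv()] (or any
#'   data frames sharing metric columns), row-aligned.
#' @return A tibble of per-metric deltas with the same metric column names.
#' @export
hrv_reactivity <- function(on_task, rest) {
  cols <- intersect(intersect(names(on_task), names(rest)),
                    session_metric_cols)
  if (!length(cols)) {
    abort_argument("No shared metric columns between `on_task` and `rest`.")
  }
  if (nrow(on_task) != nrow(rest)) {
    abort_argument("`on_task` and `rest` must have the same number of rows.")
  }
  out <- purrr::map(cols, function(cl) on_task[[cl]] - rest[[cl]])
  names(out) <- cols
  tibble::as_tibble(out)
}
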