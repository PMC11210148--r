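#' Time-domain vm-HRV metrics
#'
#' `mean_rr()` is the arithmetic mean of the intervals (ms) and must be
#' computed on the *undetrended* corrected series; `mean_hr()` is
#' `60000 / mRR` in beats per minute. `rmssd()` is the root mean square of
#' successive interval differences, and `poincare_sd1()` the Poincare-plot
#' dispersion perpendicular to the identity line, computed in its RMS form
#' `sqrt(mean(diff^2) / 2)` so the identity `SD1 = RMSSD / sqrt(2)` holds
#' exactly.
#'
#' @param x An [rr_series()], an `hrv_tachogram`, or a numeric vector of
#'   intervals / detrended tachogram values (ms).
#' @return A single value in ms (bpm for `mean_hr()`).
#' @examples
#' rmssd(c(800, 810, 790, 800)) # 14.14 ms
#' @name time_domain
NULL

metric_values <- function(x) {
  if (inherits(x, "hrv_tachogram")) return(x$value_ms)
  if (inherits(x, "rr_series") || is.data.frame(x)) {
    return(as_rr_series(x)$rr_ms)
  }
  if (is.numeric(x)) return(as.numeric(x))
  abort_argument("Expected an rr_series, hrv_tachogram or numeric vector.")
}

#' @rdname time_domain
#' @export
mean_rr <- function(x) {
  v <- metric_values(x)
  if (length(v) < 1L) abort_insufficient("mean RR needs at least one beat.")
  mean(v)
}

#' @rdname time_domain
#' @export
mean_hr <- function(x) 60000 / mean_rr(x)

#' @rdname time_domain
#' @export
rmssd <- function(x) {
  v <- metric_values(x)
  if (length(v) < 2L) abort_insufficient("RMSSD needs at least two beats.")
  sqrt(mean(diff(v)^2))
}

#' @rdname time_domain
#' @export
poincare_sd1 <- function(x) {
  v <- metric_values(x)
  if (length(v) < 2L) abort_insufficient("SD1 needs at least two beats.")
  sqrt(mean(diff(v)^2) / 2)
}

# SD2 from the Poincare identity 2*SDNN^2 = SD1^2 + SD2^2 (population SDNN)
poincare_sd2 <- function(x) {
  v <- metric_values(x)
  if (length(v) < 2L) abort_insufficient("SD2 needs at least two beats.")
  sdnn2 <- mean((v - mean(v))^2)
  sd1 <- poincare_sd1(v)
  sqrt(max(0, 2 * sdnn2 - sd1^2))
}

#' Normative resting values for the parasympathetic tone index
#'
#' Configurable population means and SDs used to standardize mean R-R,
#' RMSSD and normalized SD1 in [pns_index()]. The defaults are round
#' resting-population values drawn from published short-term normative
#' ranges in healthy adults (mean RR 926 +/- 90 ms, RMSSD 42 +/- 25 ms,
#' SD1/(SD1+SD2) 0.30 +/- 0.10); the index's *structure* is what matters
#' downstream, its calibration is configuration.
#'
#' @param mrr_mean,mrr_sd Mean R-R normative mean and SD (ms).
#' @param rmssd_mean,rmssd_sd RMSSD normative mean and SD (ms).
#' @param sd1nu_mean,sd1nu_sd Normalized SD1 normative mean and SD.
#' @return A `pns_normals` list.
#' @export
pns_normals <- function(mrr_mean = 926, mrr_sd = 90,
                        rmssd_mean = 42, rmssd_sd = 25,
                        sd1nu_mean = 0.30, sd1nu_sd = 0.10) {
  vals <- list(mrr_mean = mrr_mean, mrr_sd = mrr_sd,
               rmssd_mean = rmssd_mean, rmssd_sd = rmssd_sd,
               sd1nu_mean = sd1nu_mean, sd1nu_sd = sd1nu_sd)
  for (nm in c("mrr_sd", "rmssd_sd", "sd1nu_sd")) {
    if (!is_scalar_number(vals[[nm]]) || vals[[nm]] <= 0) {
      abort_argument(sprintf("`%s` must be a positive number.", nm))
    }
  }
  structure(vals, class = "pns_normals")
}

#' Parasympathetic tone index
#'
#' Compares parasympathetic activity to normal resting values: the
#' equal-weight mean of three standardized deviations, `z(mRR)`, `z(RMSSD)`
#' and `z(SD1nu)` with `SD1nu = SD1 / (SD1 + SD2)`. Zero means "at the
#' normative resting mean"; +1 means each component sits one normative SD
#' above it.
#'
#' @param mrr Mean R-R interval (ms).
#' @param rmssd RMSSD (ms).
#' @param sd1 Poincare SD1 (ms).
#' @param sd2 Poincare SD2 (ms).
#' @param normals A [pns_normals()].
#' @return The dimensionless index.
#' @examples
#' nm <- pns_normals()
#' pns_index(nm$mrr_mean, nm$rmssd_mean, 30, 70, nm) # 0 at the normals
#' @export
pns_index <- function(mrr, rmssd, sd1, sd2, normals = pns_normals()) {
  stopifnot(inherits(normals, "pns_normals"))
  if (!is_scalar_number(mrr) || !is_scalar_number(rmssd) ||
      !is_scalar_number(sd1) || !is_scalar_number(sd2)) {
    abort_argument("All pns_index components must be single numbers.")
  }
  if (sd1 + sd2 <= 0) {
    abort_undefined_metric("SD1 + SD2 is zero: normalized SD1 undefined.")
  }
  sd1nu <- sd1 / (sd1 + sd2)
  mean(c(
    (mrr - normals$mrr_mean) / normals$mrr_sd,
    (rmssd - normals$rmssd_mean) / normals$rmssd_sd,
    (sd1nu - normals$sd1nu_mean) / normals$sd1nu_sd
  ))
}

#' Compute the full vm-HRV metric set for one segment
#'
#' Orchestrates the per-segment pipeline: artifact detection and correction,
#' the data-quality gate, mean R-R on the undetrended corrected series,
#' smoothness-priors detrending, then RMSSD, SD1, the Welch spectrum with HF
#' and normalized HF power, and the parasympathetic tone index. Segments
#' failing the gate (or any stage) yield a row of missing metrics with the
#' reason recorded, never zeros.
#'
#' @param series An [rr_series()].
#' @param cfg A [detrend_config()].
#' @param bands A [spectral_bands()].
#' @param normals A [pns_normals()].
#' @param threshold_scale Artifact-detection threshold multiplier.
#' @param gate_fraction Quality-gate limit on the corrected fraction.
#' @param window_s Welch segment length; default `min(150, duration)`.
#' @return A one-row tibble with `mrr_ms`, `mean_hr_bpm`, `rmssd_ms`,
#'   `hf_ms2`, `hf_nu`, `sd1_ms`, `pns_index`, `fraction_corrected`,
#'   `quality_pass` and `fail_reason`.
#' @export
compute_hrv <- function(series, cfg = detrend_config(),
                        bands = spectral_bands(), normals = pns_normals(),
                        threshold_scale = 5.2, gate_fraction = 0.05,
                        window_s = NULL) {
  missing_row <- function(reason, fraction = NA_real_, pass = FALSE) {
    tibble::tibble(
      mrr_ms = NA_real_, mean_hr_bpm = NA_real_, rmssd_ms = NA_real_,
      hf_ms2 = NA_real_, hf_nu = NA_real_, sd1_ms = NA_real_,
      pns_index = NA_real_, fraction_corrected = fraction,
      quality_pass = pass, fail_reason = reason
    )
  }
  res <- tryCatch({
    series <- as_rr_series(series)
    report <- detect_artifacts(series, threshold_scale = threshold_scale)
    if (!quality_gate(report, gate_fraction)) {
      return(missing_row(
        sprintf("quality gate: %.1f%% of beats corrected (limit %.0f%%)",
                100 * report$fraction_corrected, 100 * gate_fraction),
        fraction = report$fraction_corrected
      ))
    }
    corrected <- correct_beats(series, report)
    mrr <- mean_rr(corrected)
    tach <- detrend_sp(corrected, cfg)
    rms <- rmssd(tach)
    sd1 <- poincare_sd1(tach)
    sd2 <- poincare_sd2(tach)
    spec <- psd_welch(tach, window_s = window_s, bands = bands)
    hf <- attr(spec, "band_powers")$hf
    hfn <- tryCatch(hf_nu(spec), vmhrv_error_undefined_metric = function(e) NA_real_)
    pns <- tryCatch(pns_index(mrr, rms, sd1, sd2, normals),
                    vmhrv_error_undefined_metric = function(e) NA_real_)
    tibble::tibble(
      mrr_ms = mrr, mean_hr_bpm = 60000 / mrr, rmssd_ms = rms,
      hf_ms2 = hf, hf_nu = hfn, sd1_ms = sd1, pns_index = pns,
      fraction_corrected = report$fraction_corrected,
      quality_pass = TRUE, fail_reason = NA_character_
    )
  }, vmhrv_error = function(e) missing_row(conditionMessage(e)))
  res
}
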