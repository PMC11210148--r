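#' Standard HRV frequency bands
#'
#' Very-low (0-0.04 Hz), low (0.04-0.15 Hz) and high (0.15-0.4 Hz) frequency
#' bands; contiguous, non-overlapping, ordered.
#'
#' @param vlf,lf,hf Two-element numeric vectors `(lower, upper)` in Hz.
#' @return A `spectral_bands` list.
#' @export
spectral_bands <- function(vlf = c(0, 0.04), lf = c(0.04, 0.15),
                           hf = c(0.15, 0.40)) {
  bands <- list(vlf = vlf, lf = lf, hf = hf)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || !is.numeric(b) || b[1] >= b[2]) {
      abort_argument(sprintf("Band `%s` must be (lower, upper) with lower < upper.", nm))
    }
  }
  if (vlf[2] != lf[1] || lf[2] != hf[1]) {
    abort_argument("Bands must be contiguous: vlf|lf|hf.")
  }
  structure(bands, class = "spectral_bands")
}

#' Welch power spectral density of a tachogram
#'
#' Estimates the power spectrum of the (detrended) tachogram by Welch's
#' method: cubic-spline resampling to an even grid, Hann-tapered segments
#' with 50% overlap, averaged one-sided periodograms. The segment length
#' defaults to `min(150 s, duration)`, so on 60-s on-task windows the
#' estimate degrades gracefully to a single tapered periodogram; the coarse
#' resolution there is acceptable because only band *integrals* are used.
#'
#' @param x An `hrv_tachogram` from [detrend_sp()] (its even grid is reused),
#'   an [rr_series()] (resampled internally), or a plain numeric vector
#'   already on an even grid.
#' @param resample_hz Grid rate in Hz when `x` must be resampled (default 4).
#' @param window_s Welch segment length in seconds; default
#'   `min(150, duration)`.
#' @param overlap Segment overlap fraction (default 0.5).
#' @param bands A [spectral_bands()].
#' @return An `hrv_psd`: tibble with `freq_hz` and `psd_ms2_hz`, with
#'   `total_power` and `band_powers` (ms^2, rectangle rule) as attributes,
#'   accessors [band_powers()] and [total_power()].
#' @export
psd_welch <- function(x, resample_hz = 4, window_s = NULL, overlap = 0.5,
                      bands = spectral_bands()) {
  if (inherits(x, "hrv_tachogram")) {
    grid <- attr(x, "grid")
    v <- grid$value_ms
    fs <- attr(x, "fs")
  } else if (inherits(x, "rr_series") || is.data.frame(x)) {
    s <- as_rr_series(x)
    if (nrow(s) < 3L) abort_insufficient("Need at least 3 beats for a spectrum.")
    t_grid <- seq(s$t_s[1], s$t_s[nrow(s)], by = 1 / resample_hz)
    v <- stats::spline(s$t_s, s$rr_ms, xout = t_grid, method = "fmm")$y
    fs <- resample_hz
  } else if (is.numeric(x)) {
    v <- as.numeric(x)
    fs <- resample_hz
  } else {
    abort_argument("`x` must be an hrv_tachogram, rr_series or numeric vector.")
  }
  check_number(overlap, "overlap", min = 0, max = 1, inclusive = c(TRUE, FALSE))
  dur <- length(v) / fs
  if (is.null(window_s)) window_s <- min(150, dur)
  check_number(window_s, "window_s", min = 0, inclusive = c(FALSE, TRUE))
  nper <- round(window_s * fs)
  if (nper > length(v)) {
    abort_insufficient(sprintf(
      "Segment of %.1f s is shorter than the %.1f s Welch window.",
      dur, window_s))
  }
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, length(v) - nper + 1L, by = step)
  w <- hann_window(nper)
  scale <- fs * sum(w^2) # one-sided density normalization
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- v[s0:(s0 + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- abs(stats::fft(seg))^2 / scale
    half <- spec[seq_len(nfreq)]
    # fold two-sided density into one-sided (not DC, not Nyquist if even)
    mult <- rep(2, nfreq)
    mult[1] <- 1
    if (nper %% 2L == 0L) mult[nfreq] <- 1
    acc <- acc + half * mult
  }
  psd <- acc / length(starts)
  freq <- seq(0, by = fs / nper, length.out = nfreq)
  df <- fs / nper
  bp <- vapply(bands, function(b) {
    sum(psd[freq > b[1] & freq <= b[2]]) * df
  }, numeric(1))
  structure(
    tibble::tibble(freq_hz = freq, psd_ms2_hz = psd),
    total_power = sum(psd[freq > 0]) * df,
    band_powers = as.list(bp),
    bands = bands,
    df = df,
    class = c("hrv_psd", class(tibble::tibble()))
  )
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' @rdname psd_welch
#' @param spec An `hrv_psd`.
#' @export
band_powers <- function(spec) {
  stopifnot(inherits(spec, "hrv_psd"))
  tibble::as_tibble(attr(spec, "band_powers"))
}

#' @rdname psd_welch
#' @export
total_power <- function(spec) {
  stopifnot(inherits(spec, "hrv_psd"))
  attr(spec, "total_power")
}

#' Normalized high-frequency power
#'
#' `HF[n.u.] = HF / (total power - VLF)`: the share of high-frequency power
#' in the non-VLF spectrum, a dimensionless value in `[0, 1]`.
#'
#' @param spec An `hrv_psd`, or a named list/vector with `hf`, `vlf` and
#'   `total` entries (ms^2).
#' @return The normalized HF power.
#' @examples
#' hf_nu(list(hf = 400, vlf = 500, total = 2000)) # 0.2667
#' @export
hf_nu <- function(spec) {
  if (inherits(spec, "hrv_psd")) {
    bp <- attr(spec, "band_powers")
    hf <- bp$hf
    vlf <- bp$vlf
    total <- attr(spec, "total_power")
  } else {
    spec <- as.list(spec)
    hf <- spec$hf
    vlf <- spec$vlf
    total <- spec$total
  }
  denom <- total - vlf
  if (!is.finite(denom) || denom <= 0) {
    abort_undefined_metric(
      "HF n.u. undefined: total power does not exceed VLF power.")
  }
  min(1, max(0, hf / denom))
}
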