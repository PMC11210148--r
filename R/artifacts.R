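#' Detect abnormal beats in an R-R series
#'
#' Flags ectopic, missed, extra and misaligned beats with the
#' successive-difference (dRR) scheme used by automated HRV software: each
#' beat's deviation is compared against a time-varying threshold equal to
#' `threshold_scale` times the local quartile deviation of the dRR series
#' (and of the deviation from a running 11-beat median). Flagged beats are
#' then subtyped by pattern: a single interval near twice the local median is
#' a missed beat, a short pair summing to the local median is an extra
#' (spurious) detection, and a short-long alternation is an ectopic or
#' misaligned beat.
#'
#' A simpler `"median"` detector (flag beats deviating from the running
#' median by more than `median_tol` of it) is available for testing and for
#' very short segments.
#'
#' @param series An [rr_series()] with at least 10 beats.
#' @param threshold_scale Multiplier on the local quartile deviation
#'   (default 5.2).
#' @param method `"quartile"` (default) or `"median"`.
#' @param median_tol Relative deviation tolerance for the median detector.
#' @return A `correction_report`: per-beat `labels`
#'   (normal/ectopic/missed/extra/misaligned), `n_input_beats`,
#'   `n_corrected`, and `fraction_corrected`.
#' @export
detect_artifacts <- function(series, threshold_scale = 5.2,
                             method = c("quartile", "median"),
                             median_tol = 0.3) {
  series <- as_rr_series(series)
  method <- match.arg(method)
  n <- nrow(series)
  if (n < 10L) {
    abort_insufficient(sprintf(
      "Artifact detection needs at least 10 beats (got %d).", n))
  }
  check_number(threshold_scale, "threshold_scale", min = 0,
               inclusive = c(FALSE, TRUE))
  rr <- series$rr_ms
  med <- running_median(rr, 11L)

  if (method == "quartile") {
    drr <- c(0, diff(rr))
    th1 <- threshold_scale * pmax(rolling_qd(drr, 91L), 0.01)
    dmed <- rr - med
    th2 <- threshold_scale * pmax(rolling_qd(dmed, 91L), 0.01)
    drrs <- drr / th1
    dmeds <- dmed / th2
    # the median-deviation series carries the flag: a single abnormal beat
    # perturbs dRR at two positions but dMed at one, so flagging on dMed
    # avoids cascading onto the (normal) neighbour; dRRs still drives the
    # subtype patterns below
    flagged <- abs(dmeds) > 1
  } else {
    dev <- abs(rr - med) / med
    flagged <- dev > median_tol
    drrs <- c(0, diff(rr)) / pmax(med * median_tol, 0.01)
  }

  labels <- rep("normal", n)
  for (i in which(flagged)) {
    if (labels[i] != "normal") next
    if (rr[i] >= 1.5 * med[i]) {
      labels[i] <- "missed"
    } else if (rr[i] <= 0.6 * med[i] && i < n && rr[i + 1] <= 0.8 * med[i] &&
               abs(rr[i] + rr[i + 1] - med[i]) < 0.3 * med[i]) {
      labels[i] <- "extra"
      labels[i + 1] <- "extra"
    } else if ((i < n && sign(drrs[i]) * sign(drrs[min(i + 1, n)]) < 0 &&
                abs(drrs[min(i + 1, n)]) > 1) ||
               (i > 1 && sign(drrs[i]) * sign(drrs[i - 1]) < 0 &&
                abs(drrs[i - 1]) > 1)) {
      labels[i] <- "ectopic"
    } else {
      labels[i] <- "misaligned"
    }
  }

  new_correction_report(series, labels,
                        threshold_scale = threshold_scale, method = method)
}

new_correction_report <- function(series, labels, corrected = NULL, ...) {
  n <- nrow(series)
  n_corr <- sum(labels != "normal")
  structure(
    list(
      labels = labels,
      series = series,
      corrected = corrected,
      n_input_beats = n,
      n_corrected = n_corr,
      fraction_corrected = n_corr / n,
      settings = list(...)
    ),
    class = "correction_report"
  )
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf(
    "<correction_report: %d beats, %d flagged (%.2f%%)>\n",
    x$n_input_beats, x$n_corrected, 100 * x$fraction_corrected
  ))
  tab <- table(factor(x$labels, levels = c("normal", "ectopic", "missed",
                                           "extra", "misaligned")))
  print(tab)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.correction_report <- function(x, ...) {
  tibble::tibble(
    beat = seq_len(x$n_input_beats),
    rr_ms = x$series$rr_ms,
    label = x$labels
  )
}

# rolling quartile deviation (IQR/2) over a centred window
rolling_qd <- function(x, k = 91L) {
  n <- length(x)
  half <- k %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    w <- x[lo:hi]
    diff(stats::quantile(w, c(0.25, 0.75), names = FALSE, type = 7)) / 2
  }, numeric(1))
}

#' Correct flagged beats
#'
#' Applies the label-specific corrections: missed-beat intervals are split
#' into the implied number of true beats (spline-consistent apportioning of
#' the original duration), extra detections are merged back into one
#' interval, and ectopic/misaligned beats are replaced by local interpolation
#' rescaled so the affected span keeps its duration. Total recording duration
#' is preserved.
#'
#' @param series The [rr_series()] the report was computed on.
#' @param report A `correction_report` from [detect_artifacts()].
#' @return The corrected [rr_series()].
#' @export
correct_beats <- function(series, report) {
  series <- as_rr_series(series)
  stopifnot(inherits(report, "correction_report"))
  labels <- report$labels
  n <- nrow(series)
  if (length(labels) != n) {
    abort_argument("Report labels do not match the series length.")
  }
  if (report$fraction_corrected > 0.5) {
    abort_vmhrv(sprintf(
      "Signal uncorrectable: %.0f%% of beats flagged (limit 50%%).",
      100 * report$fraction_corrected), "vmhrv_error_uncorrectable")
  }
  rr <- series$rr_ms
  if (all(labels == "normal")) {
    return(rr_series(rr, meta = rr_meta(series)))
  }

  normal_idx <- which(labels == "normal")
  if (length(normal_idx) < 2L) {
    abort_vmhrv("Too few normal beats to interpolate corrections.",
                "vmhrv_error_uncorrectable")
  }
  expected_at <- function(xout) {
    est <- if (length(normal_idx) >= 4L) {
      stats::spline(normal_idx, rr[normal_idx], xout = xout,
                    method = "natural")$y
    } else {
      stats::approx(normal_idx, rr[normal_idx], xout = xout, rule = 2)$y
    }
    bad <- !is.finite(est) | est <= 0
    if (any(bad)) {
      est[bad] <- stats::approx(normal_idx, rr[normal_idx],
                                xout = xout[bad], rule = 2)$y
    }
    est
  }

  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    lab <- labels[i]
    if (lab == "normal") {
      out[[i]] <- rr[i]
      i <- i + 1L
    } else if (lab == "extra") {
      j <- i
      while (j < n && labels[j + 1L] == "extra") j <- j + 1L
      out[[i]] <- sum(rr[i:j]) # merge the spurious split back together
      i <- j + 1L
    } else if (lab == "missed") {
      exp_rr <- expected_at(i)
      m <- max(2L, round(rr[i] / exp_rr))
      pos <- i - 0.5 + (seq_len(m) - 0.5) / m
      w <- expected_at(pos)
      out[[i]] <- rr[i] * w / sum(w)
      i <- i + 1L
    } else { # ectopic / misaligned: replace a contiguous run, keep its span
      j <- i
      while (j < n && labels[j + 1L] %in% c("ectopic", "misaligned")) {
        j <- j + 1L
      }
      est <- expected_at(i:j)
      out[[i]] <- est * sum(rr[i:j]) / sum(est)
      i <- j + 1L
    }
  }
  rr_series(unlist(out), meta = rr_meta(series))
}

#' Convenience wrapper: detect and correct in one call
#'
#' @inheritParams detect_artifacts
#' @param ... Passed to [detect_artifacts()].
#' @return A `correction_report` whose `corrected` field holds the corrected
#'   series.
#' @export
correct_rr <- function(series, ...) {
  series <- as_rr_series(series)
  report <- detect_artifacts(series, ...)
  report$corrected <- correct_beats(series, report)
  report
}

#' Data-quality gate on the corrected fraction
#'
#' A segment passes when strictly fewer than `max_fraction` of its beats
#' needed correction; recordings failing the gate are excluded from the
#' reliability and validity analysis rather than analyzed.
#'
#' @param report A `correction_report`.
#' @param max_fraction Exclusion threshold on the corrected fraction
#'   (default 0.05, i.e. the 5% rule).
#' @return `TRUE` if the segment passes, `FALSE` otherwise.
#' @examples
#' s <- rr_series(rep(c(995, 1005), 50))
#' quality_gate(detect_artifacts(s))
#' @export
quality_gate <- function(report, max_fraction = 0.05) {
  stopifnot(inherits(report, "correction_report"))
  check_number(max_fraction, "max_fraction", min = 0, max = 1)
  report$fraction_corrected < max_fraction
}
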