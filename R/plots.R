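#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an R-R series as a tachogram
#'
#' @param object An [rr_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t_s, y = .data$rr_ms)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "time [s]", y = "R-R interval [ms]",
                  title = "Tachogram") +
    ggplot2::theme_minimal()
}

#' Plot a power spectral density with the HRV bands shaded
#'
#' @param object An `hrv_psd` from [psd_welch()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrv_psd <- function(object, ...) {
  bands <- attr(object, "bands")
  shade <- tibble::tibble(
    band = factor(names(bands), levels = names(bands)),
    xmin = vapply(bands, `[`, numeric(1), 1),
    xmax = vapply(bands, `[`, numeric(1), 2)
  )
  ggplot2::ggplot(tibble::as_tibble(object)) +
    ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf,
                   ymax = Inf, fill = .data$band),
      alpha = 0.15
    ) +
    ggplot2::geom_line(ggplot2::aes(x = .data$freq_hz,
                                    y = .data$psd_ms2_hz)) +
    ggplot2::coord_cartesian(xlim = c(0, 0.5)) +
    ggplot2::labs(x = "frequency [Hz]", y = expression(PSD ~ "[" * ms^2 / Hz * "]"),
                  fill = "band") +
    ggplot2::theme_minimal()
}

#' Plot a reliability grid as an ICC forest
#'
#' One point-range per condition (ICC with its 95% CI), coloured by
#' interpretation band, with the fair/good/excellent thresholds marked.
#'
#' @param object A [reliability_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reliability_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$estimable) |>
    dplyr::mutate(condition = paste(.data$game, .data$level, sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc, y = .data$condition,
                                   colour = .data$icc_band)) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9),
                        linetype = "dashed", colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$icc_low,
                                          xmax = .data$icc_high)) +
    ggplot2::labs(x = "ICC(3,1) with 95% CI", y = NULL,
                  colour = "band",
                  title = sprintf("Test-retest reliability: %s",
                                  attr(object, "metric"))) +
    ggplot2::theme_minimal()
}
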