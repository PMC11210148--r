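#' Intraclass correlation ICC(3,1) with exact confidence interval
#'
#' Two-way mixed-effects, single-measures, *consistency* intraclass
#' correlation for test-retest agreement:
#' \deqn{ICC(3,1) = (MS_{rows} - MS_{error}) / (MS_{rows} + (k-1) MS_{error})}
#' from the subjects-by-occasions mean squares, with the exact F-bound
#' confidence interval of the Shrout-Fleiss / McGraw-Wong lineage. Being a
#' consistency form, it ignores additive shifts between occasions.
#'
#' @param pairs An `n x k` matrix or data frame of repeated measurements
#'   (rows = subjects, columns = occasions; `k = 2` for test-retest), no
#'   missing cells, `n >= 3`.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `icc31`: a list with `icc`, `ci_low`,
#'   `ci_high`, `band` (see [classify_icc()]), `n`, `k`, `conf` and the mean
#'   squares; [tidy()] returns it as a one-row tibble.
#' @examples
#' m <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
#' icc31(m)$icc # 1: retest is test + 1, consistency form ignores the shift
#' @export
icc31 <- function(pairs, conf = 0.95) {
  m <- as.matrix(pairs)
  if (anyNA(m)) abort_validation("ICC input must have no missing cells.")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L || k < 2L) {
    abort_insufficient("ICC(3,1) needs at least 3 subjects and 2 occasions.")
  }
  check_number(conf, "conf", min = 0, max = 1, inclusive = c(FALSE, FALSE))
  ms <- icc_mean_squares(m)
  if (ms$msr <= 0 && ms$mse <= 0) {
    abort_undefined_metric("ICC undefined: zero total variance.")
  }
  icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  a <- 1 - conf
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  f_obs <- if (ms$mse > 0) ms$msr / ms$mse else Inf
  fl <- f_obs / stats::qf(1 - a / 2, df1, df2)
  fu <- f_obs * stats::qf(1 - a / 2, df2, df1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  ci[!is.finite(ci)] <- 1
  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2],
         band = classify_icc(icc), n = n, k = k, conf = conf,
         msr = ms$msr, msc = ms$msc, mse = ms$mse),
    class = "icc31"
  )
}

icc_mean_squares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  g <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm_ - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  list(
    msr = ssr / (n - 1),
    msc = ssc / (k - 1),
    mse = max(0, sse) / ((n - 1) * (k - 1))
  )
}

#' @export
print.icc31 <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f  %d%% CI [%.3f, %.3f]  (%s; n = %d, k = %d)\n",
              x$icc, round(100 * x$conf), x$ci_low, x$ci_high, x$band,
              x$n, x$k))
  invisible(x)
}

#' @export
tidy.icc31 <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
    band = x$band, n = x$n, k = x$k, conf = x$conf
  )
}

#' @importFrom generics glance
#' @export
glance.icc31 <- function(x, ...) tidy(x, ...)

#' Interpret an ICC estimate
#'
#' Bands: poor (< 0.50), fair (0.50-0.75), good (0.75-0.90), excellent
#' (>= 0.90); boundaries are left-closed.
#'
#' @param icc ICC estimate(s), each `<= 1`.
#' @return Character vector of bands.
#' @examples
#' classify_icc(c(0.49, 0.5, 0.76, 0.9))
#' @export
classify_icc <- function(icc) {
  if (any(icc > 1 + 1e-12, na.rm = TRUE)) {
    abort_argument("ICC cannot exceed 1.")
  }
  cut_band(icc, c(0.5, 0.75, 0.9),
           c("poor", "fair", "good", "excellent"))
}

cut_band <- function(x, breaks, labels) {
  out <- labels[findInterval(x, breaks) + 1L]
  out[is.na(x)] <- NA_character_
  out
}

#' Standard error of measurement and smallest detectable difference
#'
#' Absolute reliability on the measurement scale: `SEM = SD * sqrt(1 - ICC)`
#' with SD the pooled standard deviation across the two measurement
#' occasions, and `SDD = SEM * 1.96 * sqrt(2)` (= 2.77180 * SEM), the
#' smallest change exceeding measurement noise at 95% confidence for a
#' difference of two measurements. [normalize_pct()] expresses either as a
#' percentage of the combined mean of both occasions.
#'
#' @param pairs The `n x 2` measurement matrix, or a single pooled SD.
#' @param icc The ICC(3,1) estimate (`<= 1`).
#' @return `sem_abs()`: SEM in metric units.
#' @examples
#' sem_abs(10, icc = 0.75) # 5
#' sdd_abs(10)             # 27.718
#' @export
sem_abs <- function(pairs, icc) {
  if (!is_scalar_number(icc) || icc > 1 + 1e-12) {
    abort_argument("`icc` must be a single number <= 1.")
  }
  sd_pooled <- if (is_scalar_number(pairs)) {
    pairs
  } else {
    m <- as.matrix(pairs)
    sqrt(mean(apply(m, 2, stats::var)))
  }
  sd_pooled * sqrt(max(0, 1 - icc))
}

#' @rdname sem_abs
#' @param sem SEM in metric units.
#' @return `sdd_abs()`: SDD in metric units.
#' @export
sdd_abs <- function(sem) {
  if (any(sem < 0, na.rm = TRUE)) abort_argument("`sem` must be >= 0.")
  sem * 1.96 * sqrt(2)
}

#' @rdname sem_abs
#' @param x Value in metric units (a SEM or SDD).
#' @param grand_mean Combined mean of both measurement occasions.
#' @return `normalize_pct()`: `100 * x / grand_mean`.
#' @export
normalize_pct <- function(x, grand_mean) {
  if (!is_scalar_number(grand_mean) || grand_mean == 0) {
    abort_undefined_metric(
      "Percentage undefined: grand mean is zero or not a number.")
  }
  100 * x / grand_mean
}

#' Sample size for estimating an ICC with desired precision
#'
#' Plans the number of subjects so the `conf`-level confidence interval of
#' an anticipated ICC has width at most `width` with probability
#' `assurance`. Starts from Bonett's closed form
#' `n = 8 z^2 (1-rho)^2 (1+(k-1)rho)^2 / (k (k-1) w^2) + 1` and then adjusts
#' iteratively against the exact F-bound interval: with 50% assurance the
#' criterion is the *expected* CI width (the closed form's own target, which
#' the approximation underestimates at k = 2); with higher assurance the
#' criterion is the corresponding quantile of the CI-width sampling
#' distribution, both evaluated analytically from the scaled-F sampling
#' distribution of the ICC estimator.
#'
#' @param rho0 Anticipated ICC, in (0, 1).
#' @param width Desired CI width, in (0, 2).
#' @param conf Confidence level of the interval (default 0.95).
#' @param assurance Probability of achieving the precision (default 0.5).
#' @param k Measurements per subject (default 2).
#' @return Minimum number of subjects (integer).
#' @examples
#' sample_size_icc(0.75, width = 0.3) # 38
#' @export
sample_size_icc <- function(rho0, width, conf = 0.95, assurance = 0.5,
                            k = 2) {
  check_number(rho0, "rho0", min = 0, max = 1, inclusive = c(FALSE, FALSE))
  check_number(width, "width", min = 0, max = 2, inclusive = c(FALSE, FALSE))
  check_number(conf, "conf", min = 0, max = 1, inclusive = c(FALSE, FALSE))
  check_number(assurance, "assurance", min = 0, max = 1,
               inclusive = c(FALSE, FALSE))
  if (!is_scalar_number(k) || k < 2 || k != round(k)) {
    abort_argument("`k` must be an integer >= 2.")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n0 <- ceiling(8 * z^2 * (1 - rho0)^2 * (1 + (k - 1) * rho0)^2 /
                  (k * (k - 1) * width^2) + 1)
  n0 <- max(n0, 4L)

  meets <- function(n) {
    if (assurance <= 0.5) {
      expected_ci_width(n, rho0, k, conf) <= width
    } else {
      width_quantile(n, rho0, k, conf, assurance) <= width
    }
  }
  n <- n0
  if (meets(n)) {
    while (n > 4L && meets(n - 1L)) n <- n - 1L
  } else {
    while (!meets(n)) {
      n <- n + 1L
      if (n > 1e6) abort_argument("Requested ICC precision is infeasible.")
    }
  }
  as.integer(n)
}

# exact F-bound CI width at an observed consistency ICC r
icc_ci_width_at <- function(n, r, k, conf) {
  a <- 1 - conf
  f_obs <- (1 + (k - 1) * r) / (1 - r)
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fl <- f_obs / stats::qf(1 - a / 2, df1, df2)
  fu <- f_obs * stats::qf(1 - a / 2, df2, df1)
  (fu - 1) / (fu + k - 1) - (fl - 1) / (fl + k - 1)
}

# E[width] over the sampling distribution of the ICC estimator: the ANOVA F
# ratio is tau * F(n-1, (n-1)(k-1)) with tau = (1+(k-1)rho)/(1-rho)
expected_ci_width <- function(n, rho, k, conf) {
  tau <- (1 + (k - 1) * rho) / (1 - rho)
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  f <- function(q) {
    fv <- tau * stats::qf(q, df1, df2)
    r <- (fv - 1) / (fv + k - 1)
    icc_ci_width_at(n, r, k, conf)
  }
  stats::integrate(Vectorize(f), 1e-6, 1 - 1e-6,
                   subdivisions = 500L)$value
}

# width is decreasing in r, so its gamma-quantile is the width at the
# (1-gamma)-quantile of the estimator
width_quantile <- function(n, rho, k, conf, gamma) {
  tau <- (1 + (k - 1) * rho) / (1 - rho)
  fv <- tau * stats::qf(1 - gamma, n - 1, (n - 1) * (k - 1))
  r <- (fv - 1) / (fv + k - 1)
  icc_ci_width_at(n, r, k, conf)
}
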