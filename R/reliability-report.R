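#' Three-level test-retest reliability report
#'
#' Assembles the full reliability grid for one metric across every
#' `phase x game x level` condition of a session table, mirroring the
#' three-level approach to test-retest assessment:
#'
#' 1. *Systematic error*: a two-way within-subject ANOVA
#'    (timepoint x demand level) per game - parametric with Mauchly /
#'    Greenhouse-Geisser handling, or the rank-based ANOVA-type statistic
#'    when any cell fails Shapiro-Wilk screening.
#' 2. *Relative reliability*: ICC(3,1) with its exact 95% CI and
#'    interpretation band per condition.
#' 3. *Absolute reliability*: SEM, SEM%, SDD and SDD% per condition, the
#'    percentages normalized by the combined mean of both occasions.
#'
#' Only rows passing the data-quality gate and belonging to the three
#' standardized demand levels enter; subjects are dropped pairwise-complete
#' per condition for the ICC/SEM block and complete-case per game for the
#' ANOVA. Conditions with fewer than 3 complete pairs are flagged
#' not-estimable.
#'
#' @param sessions A session table (see [read_session_table()]) with metric
#'   columns and `quality_pass`.
#' @param metric Name of the metric column to analyze (e.g. `"mrr_ms"`).
#' @param conf ICC confidence level (default 0.95).
#' @param alpha Significance threshold for routing and Mauchly (default
#'   0.05).
#' @return A tibble of class `reliability_report` with one row per
#'   `phase x game x level`: sample size, branch, descriptives per occasion
#'   (mean +/- SD or median (IQR) following the routing), the game-level
#'   ANOVA timepoint effect, ICC + CI + band, SEM, SEM%, SDD, SDD%, and an
#'   `estimable` flag. [glance()] summarizes per-metric means and ranges.
#' @export
reliability_report <- function(sessions, metric, conf = 0.95, alpha = 0.05) {
  sessions <- validate_session_table(sessions)
  if (!metric %in% names(sessions)) {
    abort_argument(sprintf("Metric column `%s` not found.", metric))
  }
  dat <- sessions |>
    dplyr::filter(.data$level %in% analysis_levels(),
                  !isFALSE(.data$quality_pass) & !is.na(.data$quality_pass)) |>
    dplyr::transmute(
      subject = as.character(.data$subject_id),
      phase = .data$phase, game = .data$game,
      level = as.character(.data$level),
      timepoint = as.character(.data$timepoint),
      value = .data[[metric]]
    ) |>
    dplyr::filter(!is.na(.data$value))

  grid <- dat |> dplyr::distinct(.data$phase, .data$game)
  rows <- purrr::pmap(grid, function(phase, game) {
    gdat <- dat[dat$phase == phase & dat$game == game, ]
    reliability_for_game(gdat, phase, game, conf = conf, alpha = alpha)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, metric = metric,
            class = c("reliability_report", class(tibble::tibble())))
}

reliability_for_game <- function(gdat, phase, game, conf, alpha) {
  levels_here <- intersect(analysis_levels(), unique(gdat$level))
  branch <- route_test(gdat, alpha = alpha)

  # ANOVA on subjects complete across all cells of this game
  complete <- gdat |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n == 2L * length(levels_here)) |>
    dplyr::pull(.data$subject)
  adat <- gdat[gdat$subject %in% complete, ]
  om <- NULL
  if (length(complete) >= 3L && length(levels_here) >= 2L) {
    om <- tryCatch(
      if (branch == "parametric") rm_anova_2way(adat, sphericity_alpha = alpha)
      else rank_ats_anova(adat),
      vmhrv_error = function(e) NULL
    )
  }
  time_stat <- if (!is.null(om)) om$statistic[om$term == "timepoint"] else NA_real_
  time_p <- if (!is.null(om)) om$p.value[om$term == "timepoint"] else NA_real_
  gg_eps <- if (!is.null(om) && "epsilon" %in% names(om)) {
    om$epsilon[om$term == "level"]
  } else {
    NA_real_
  }
  mau_p <- if (!is.null(om) && "mauchly_p" %in% names(om)) {
    om$mauchly_p[om$term == "level"]
  } else {
    NA_real_
  }

  purrr::map(levels_here, function(lv) {
    wide <- gdat |>
      dplyr::filter(.data$level == lv) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "timepoint",
                         values_from = "value") |>
      tidyr::drop_na()
    base <- tibble::tibble(
      phase = phase, game = game, level = lv,
      n = nrow(wide), used_nonparametric = branch == "nonparametric",
      anova_time_stat = time_stat, anova_time_p = time_p,
      gg_epsilon = gg_eps, mauchly_p = mau_p
    )
    if (nrow(wide) < 3L || !all(c("test", "retest") %in% names(wide))) {
      return(dplyr::mutate(
        base,
        desc_test = NA_character_, desc_retest = NA_character_,
        icc = NA_real_, icc_low = NA_real_, icc_high = NA_real_,
        icc_band = NA_character_, sem = NA_real_, sem_pct = NA_real_,
        sdd = NA_real_, sdd_pct = NA_real_, grand_mean = NA_real_,
        estimable = FALSE
      ))
    }
    m <- cbind(wide$test, wide$retest)
    ic <- tryCatch(icc31(m, conf = conf), vmhrv_error = function(e) NULL)
    grand <- mean(m)
    if (is.null(ic)) {
      return(dplyr::mutate(
        base,
        desc_test = describe_values(m[, 1], branch),
        desc_retest = describe_values(m[, 2], branch),
        icc = NA_real_, icc_low = NA_real_, icc_high = NA_real_,
        icc_band = NA_character_, sem = NA_real_, sem_pct = NA_real_,
        sdd = NA_real_, sdd_pct = NA_real_, grand_mean = grand,
        estimable = FALSE
      ))
    }
    sem <- sem_abs(m, ic$icc)
    sdd <- sdd_abs(sem)
    pct <- function(x) {
      tryCatch(normalize_pct(x, grand), vmhrv_error = function(e) NA_real_)
    }
    dplyr::mutate(
      base,
      desc_test = describe_values(m[, 1], branch),
      desc_retest = describe_values(m[, 2], branch),
      icc = ic$icc, icc_low = ic$ci_low, icc_high = ic$ci_high,
      icc_band = ic$band, sem = sem, sem_pct = pct(sem),
      sdd = sdd, sdd_pct = pct(sdd), grand_mean = grand,
      estimable = TRUE
    )
  }) |>
    dplyr::bind_rows()
}

describe_values <- function(v, branch) {
  if (branch == "parametric") {
    sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
  } else {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.1f (%.1f)", q[2], q[3] - q[1])
  }
}

#' @export
glance.reliability_report <- function(x, ...) {
  est <- x[x$estimable %in% TRUE, ]
  if (!nrow(est)) {
    return(tibble::tibble(metric = attr(x, "metric"), n_conditions = 0L))
  }
  tibble::tibble(
    metric = attr(x, "metric"),
    n_conditions = nrow(est),
    icc_mean = mean(est$icc), icc_min = min(est$icc), icc_max = max(est$icc),
    sem_pct_mean = mean(est$sem_pct, na.rm = TRUE),
    sem_pct_min = suppressWarnings(min(est$sem_pct, na.rm = TRUE)),
    sem_pct_max = suppressWarnings(max(est$sem_pct, na.rm = TRUE)),
    sdd_pct_mean = mean(est$sdd_pct, na.rm = TRUE),
    sdd_pct_min = suppressWarnings(min(est$sdd_pct, na.rm = TRUE)),
    sdd_pct_max = suppressWarnings(max(est$sdd_pct, na.rm = TRUE))
  )
}

#' @export
tidy.reliability_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Validity report across a session table
#'
#' Runs [validity_test()] for one metric per `phase x game`, using the
#' per-level ICCs of the corresponding [reliability_report()] as the
#' eligibility gate.
#'
#' @inheritParams reliability_report
#' @param reliability Optional precomputed [reliability_report()] for the
#'   same metric (computed internally when omitted).
#' @param alpha Significance level (default 0.05, two-sided).
#' @return A tibble of class `validity_report`, one row per `phase x game`
#'   with the omnibus results and a `pairwise` list-column; [tidy()] unnests
#'   the pairwise comparisons.
#' @export
validity_report <- function(sessions, metric, reliability = NULL,
                            alpha = 0.05, conf = 0.95) {
  sessions <- validate_session_table(sessions)
  if (is.null(reliability)) {
    reliability <- reliability_report(sessions, metric, conf = conf,
                                      alpha = alpha)
  }
  dat <- sessions |>
    dplyr::filter(.data$level %in% analysis_levels(),
                  !isFALSE(.data$quality_pass) & !is.na(.data$quality_pass)) |>
    dplyr::transmute(
      subject = as.character(.data$subject_id),
      phase = .data$phase, game = .data$game,
      level = as.character(.data$level),
      timepoint = as.character(.data$timepoint),
      value = .data[[metric]]
    ) |>
    dplyr::filter(!is.na(.data$value))

  grid <- dat |> dplyr::distinct(.data$phase, .data$game)
  rows <- purrr::pmap(grid, function(phase, game) {
    gdat <- dat[dat$phase == phase & dat$game == game, ]
    complete <- gdat |>
      dplyr::count(.data$subject) |>
      dplyr::filter(.data$n == 2L * length(analysis_levels())) |>
      dplyr::pull(.data$subject)
    gdat <- gdat[gdat$subject %in% complete, ]
    iccs <- reliability |>
      dplyr::filter(.data$phase == !!phase, .data$game == !!game) |>
      dplyr::arrange(match(.data$level, analysis_levels())) |>
      dplyr::pull(.data$icc)
    res <- if (length(complete) >= 3L) {
      tryCatch(validity_test(gdat, iccs, alpha = alpha),
               vmhrv_error = function(e) {
                 tibble::tibble(
                   eligible = FALSE, branch = NA_character_,
                   statistic_level = NA_real_, p_level = NA_real_,
                   p_interaction = NA_real_,
                   gate_reason = conditionMessage(e),
                   pairwise = list(tibble::tibble())
                 )
               })
    } else {
      tibble::tibble(
        eligible = FALSE, branch = NA_character_,
        statistic_level = NA_real_, p_level = NA_real_,
        p_interaction = NA_real_,
        gate_reason = "fewer than 3 complete subjects",
        pairwise = list(tibble::tibble())
      )
    }
    dplyr::bind_cols(tibble::tibble(phase = phase, game = game), res)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, metric = metric,
            class = c("validity_report", class(tibble::tibble())))
}

#' @export
tidy.validity_report <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    tidyr::unnest("pairwise", keep_empty = TRUE)
}

#' @export
glance.validity_report <- function(x, ...) {
  pw <- tidy(x)
  tibble::tibble(
    metric = attr(x, "metric"),
    n_conditions = nrow(x),
    n_eligible = sum(x$eligible, na.rm = TRUE),
    n_level_effect = sum(x$p_level <= 0.05, na.rm = TRUE),
    n_pairwise_significant = sum(pw$p_adj <= 0.05, na.rm = TRUE)
  )
}
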