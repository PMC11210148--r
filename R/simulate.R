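#' Synthetic cohort configuration
#'
#' Defines the ground-truth generative model for a test-retest exergaming
#' cohort: subject-specific baseline R-R intervals with between-subject
#' variance, a tunable target test-retest ICC (occasion noise applied to
#' the latent condition mean so the induced intraclass correlation of
#' condition-level mean RR equals `true_icc` analytically), monotone
#' demand-level effects on mean RR and on the respiratory (high-frequency)
#' oscillation amplitude, a slow trend, and optional injectable beat
#' artifacts.
#'
#' Defaults emulate an older-adult resting cohort: baseline RR 850 +/- 80 ms
#' between subjects, demand-level shifts of 0 / -50 / -100 ms (RR shortens
#' as demand rises), respiratory oscillation at 0.25 Hz with amplitude
#' 40 / 30 / 20 ms by level (vagal withdrawal with demand), a 25 ms
#' low-frequency (0.1 Hz) component, a 30 ms slow trend at 0.01 Hz, and
#' 10 ms white beat-to-beat noise.
#'
#' @param n_subjects Number of subjects (default 43).
#' @param games Game names (default the five-game battery).
#' @param levels Demand levels (fixed to easy/challenging/excessive).
#' @param phases Experimental phases to generate (default `1L`).
#' @param true_icc Target test-retest ICC of condition-level mean RR, in
#'   (0, 1].
#' @param baseline_rr_mean,baseline_rr_sd Between-subject baseline RR
#'   distribution (ms).
#' @param level_effect_rr Named additive shifts on mean RR per level (ms),
#'   monotone non-increasing with demand.
#' @param hf_amp_by_level Named respiratory-oscillation amplitudes per
#'   level (ms), monotone non-increasing with demand.
#' @param resp_freq Respiratory frequency (Hz, default 0.25).
#' @param lf_amp Low-frequency (0.1 Hz) oscillation amplitude (ms).
#' @param trend_amp Slow-trend amplitude (ms, 0.01 Hz component).
#' @param noise_sd Beat-to-beat white noise SD (ms).
#' @param artifact_rate Fraction of beats perturbed by [inject_artifacts()],
#'   `< 0.5`.
#' @param duration_s On-task recording duration (s, >= 90).
#' @param rest_duration_s Resting recording duration (s, default 300).
#' @param tlx_base Named baseline NASA-TLX subscore means per level.
#' @param seed Integer seed fixing the whole cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 43,
                          games = c("Simple", "Targets", "Tetris", "Simon",
                                    "Habitats"),
                          levels = analysis_levels(),
                          phases = 1L,
                          true_icc = 0.85,
                          baseline_rr_mean = 850, baseline_rr_sd = 80,
                          level_effect_rr = c(easy = 0, challenging = -50,
                                              excessive = -100),
                          hf_amp_by_level = c(easy = 40, challenging = 30,
                                              excessive = 20),
                          resp_freq = 0.25, lf_amp = 25, trend_amp = 30,
                          noise_sd = 10, artifact_rate = 0,
                          duration_s = 90, rest_duration_s = 300,
                          tlx_base = c(easy = 5, challenging = 9,
                                       excessive = 13),
                          seed = 1L) {
  check_number(true_icc, "true_icc", min = 0, max = 1,
               inclusive = c(FALSE, TRUE))
  check_number(baseline_rr_mean, "baseline_rr_mean", min = 0,
               inclusive = c(FALSE, TRUE))
  check_number(baseline_rr_sd, "baseline_rr_sd", min = 0)
  check_number(artifact_rate, "artifact_rate", min = 0, max = 0.5,
               inclusive = c(TRUE, FALSE))
  check_number(duration_s, "duration_s", min = 60, inclusive = c(TRUE, TRUE))
  if (!all(levels %in% names(level_effect_rr)) ||
      !all(levels %in% names(hf_amp_by_level))) {
    abort_argument("`level_effect_rr` and `hf_amp_by_level` must name every level.")
  }
  le <- level_effect_rr[levels]
  if (any(diff(le) > 0)) {
    abort_argument("`level_effect_rr` must be monotone non-increasing with demand.")
  }
  amp_sum <- max(hf_amp_by_level) + lf_amp + trend_amp
  if (baseline_rr_mean - 3 * baseline_rr_sd + min(le) - amp_sum -
      5 * noise_sd <= 0) {
    abort_argument("Configured effects can drive R-R intervals non-positive.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), games = games, levels = levels,
      phases = as.integer(phases), true_icc = true_icc,
      baseline_rr_mean = baseline_rr_mean, baseline_rr_sd = baseline_rr_sd,
      level_effect_rr = le, hf_amp_by_level = hf_amp_by_level[levels],
      resp_freq = resp_freq, lf_amp = lf_amp, trend_amp = trend_amp,
      noise_sd = noise_sd, artifact_rate = artifact_rate,
      duration_s = duration_s, rest_duration_s = rest_duration_s,
      tlx_base = tlx_base[levels], seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate one synthetic R-R recording
#'
#' Beat-by-beat construction: each interval is the baseline plus a
#' respiratory sinusoid, a low-frequency sinusoid, a slow trend and white
#' noise, all evaluated at the current cumulative beat time; intervals are
#' kept positive by construction (configurations that could produce
#' non-positive intervals are rejected).
#'
#' @param baseline_ms Mean R-R level of this recording (ms), including any
#'   condition shift.
#' @param duration_s Recording length (s).
#' @param hf_amp Respiratory oscillation amplitude (ms).
#' @param lf_amp Low-frequency (0.1 Hz) amplitude (ms).
#' @param trend_amp Slow-trend amplitude (ms).
#' @param noise_sd White beat noise SD (ms).
#' @param resp_freq Respiratory frequency (Hz).
#' @param phases Optional numeric vector of three phase offsets (radians)
#'   for the HF, LF and trend components; randomized when `NULL`.
#' @param seed Optional seed (local to this call).
#' @return An [rr_series()].
#' @export
generate_rr <- function(baseline_ms, duration_s = 90, hf_amp = 30,
                        lf_amp = 25, trend_amp = 30, noise_sd = 10,
                        resp_freq = 0.25, phases = NULL, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  check_number(baseline_ms, "baseline_ms", min = 0, inclusive = c(FALSE, TRUE))
  if (baseline_ms - hf_amp - lf_amp - trend_amp - 5 * noise_sd <= 0) {
    abort_argument("Amplitudes and noise would drive intervals non-positive.")
  }
  if (is.null(phases)) phases <- stats::runif(3, 0, 2 * pi)
  n_max <- ceiling(1000 * duration_s / (baseline_ms - hf_amp - lf_amp -
                                          trend_amp)) + 10L
  eps <- stats::rnorm(n_max, 0, noise_sd)
  rr <- numeric(n_max)
  t_ms <- 0
  n <- 0L
  while (t_ms < duration_s * 1000 && n < n_max) {
    n <- n + 1L
    t_s <- t_ms / 1000
    v <- baseline_ms +
      hf_amp * sin(2 * pi * resp_freq * t_s + phases[1]) +
      lf_amp * sin(2 * pi * 0.1 * t_s + phases[2]) +
      trend_amp * sin(2 * pi * 0.01 * t_s + phases[3]) +
      eps[n]
    v <- max(v, 1) # positivity guard; unreachable under validated configs
    rr[n] <- v
    t_ms <- t_ms + v
  }
  rr_series(rr[seq_len(n)])
}

#' Inject beat artifacts with known ground truth
#'
#' Perturbs randomly selected beats: `missed` merges two adjacent intervals
#' (a dropped detection), `extra` splits one interval in two (a spurious
#' detection), `ectopic` shifts a beat's timing by 20-40% of the local
#' interval. Returns the perturbed series together with the affected beat
#' indices (positions in the *output* series).
#'
#' @param series An [rr_series()].
#' @param rate Fraction of beats to perturb, `< 0.5`.
#' @param kinds Artifact kinds to draw from.
#' @param seed Optional seed (local to this call).
#' @return A list with `series` (perturbed [rr_series()]) and `truth` (a
#'   tibble with `kind` and `beat` index).
#' @export
inject_artifacts <- function(series, rate,
                             kinds = c("missed", "extra", "ectopic"),
                             seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  series <- as_rr_series(series)
  check_number(rate, "rate", min = 0, max = 0.5, inclusive = c(TRUE, FALSE))
  kinds <- match.arg(kinds, several.ok = TRUE)
  rr <- series$rr_ms
  n <- length(rr)
  n_events <- round(rate * n)
  if (n_events == 0L) {
    return(list(series = series,
                truth = tibble::tibble(kind = character(), beat = integer())))
  }
  # keep events 2+ beats apart and off the edges so effects don't overlap
  candidates <- 3:(n - 3)
  chosen <- integer(0)
  for (idx in sample(candidates)) {
    if (length(chosen) >= n_events) break
    if (all(abs(idx - chosen) > 2L)) chosen <- c(chosen, idx)
  }
  chosen <- sort(chosen)
  kind <- sample(kinds, length(chosen), replace = TRUE)

  # apply from the end so earlier indices stay valid, tracking the offset
  out <- as.list(rr)
  for (j in rev(seq_along(chosen))) {
    i <- chosen[j]
    if (kind[j] == "missed") {
      out[[i]] <- out[[i]] + out[[i + 1]]
      out[[i + 1]] <- NULL
    } else if (kind[j] == "extra") {
      frac <- stats::runif(1, 0.4, 0.6)
      v <- out[[i]]
      out[[i]] <- v * frac
      out <- append(out, list(v * (1 - frac)), after = i)
    } else {
      delta <- sample(c(-1, 1), 1) * stats::runif(1, 0.2, 0.4) * out[[i]]
      if (out[[i + 1]] - delta <= 50) delta <- -delta
      out[[i]] <- out[[i]] + delta
      out[[i + 1]] <- out[[i + 1]] - delta
    }
  }
  # recompute output-series indices of the injected events
  shift <- cumsum(c(0, ifelse(kind == "missed", -1L,
                              ifelse(kind == "extra", 1L, 0L))))
  beat_out <- chosen + shift[seq_along(chosen)]
  list(
    series = rr_series(unlist(out), meta = rr_meta(series)),
    truth = tibble::tibble(kind = kind, beat = as.integer(beat_out))
  )
}

#' Generate a ground-truth test-retest cohort
#'
#' Draws subject baselines from the configured between-subject
#' distribution, builds latent condition means (baseline + level shift +
#' occasion noise with the variance split implied by `true_icc`), and
#' either synthesizes full R-R recordings per session (`signals = TRUE`) or
#' fills the metric columns directly from the latent model
#' (`signals = FALSE`, for large simulation studies). NASA-TLX subscores
#' are drawn from truncated discrete distributions with monotone
#' level-shifted means. With `identical_retest = TRUE` the retest
#' recordings are byte-identical copies of the test recordings (an identity
#' cohort, useful as a reliability ceiling).
#'
#' @param cfg A [cohort_config()].
#' @param signals Generate full R-R series (default `TRUE`)?
#' @param identical_retest Duplicate test sessions as retest?
#' @return A list of class `hrv_cohort`: `sessions` (session-table tibble,
#'   with an `rr` list-column when `signals = TRUE`), `truth` (latent
#'   per-session ground truth incl. injected-artifact indices), and `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(), signals = TRUE,
                            identical_retest = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::local_seed(cfg$seed)
  sigma_b <- cfg$baseline_rr_sd
  sigma_o <- if (cfg$true_icc >= 1) 0 else sigma_b * sqrt(1 / cfg$true_icc - 1)

  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  baselines <- stats::rnorm(cfg$n_subjects, cfg$baseline_rr_mean, sigma_b)
  hf_factor <- exp(stats::rnorm(cfg$n_subjects, 0, 0.2))

  design <- tidyr::expand_grid(
    subject_id = subjects,
    phase = cfg$phases,
    game = cfg$games,
    level = cfg$levels,
    timepoint = c("test", "retest")
  )
  b_i <- baselines[match(design$subject_id, subjects)]
  shift <- cfg$level_effect_rr[design$level]
  occ <- stats::rnorm(nrow(design), 0, sigma_o)
  if (identical_retest) {
    # copy the test occasion draw onto the retest rows
    key <- paste(design$subject_id, design$phase, design$game, design$level)
    occ[design$timepoint == "retest"] <-
      occ[design$timepoint == "test"][match(key[design$timepoint == "retest"],
                                            key[design$timepoint == "test"])]
  }
  latent_mrr <- b_i + shift + occ
  hf_amp <- cfg$hf_amp_by_level[design$level] *
    hf_factor[match(design$subject_id, subjects)]

  tlx <- generate_tlx(design$level, cfg$tlx_base)

  truth <- dplyr::bind_cols(
    design,
    tibble::tibble(true_mrr_ms = latent_mrr, true_hf_amp_ms = hf_amp)
  )

  if (signals) {
    seeds <- sample.int(.Machine$integer.max, nrow(design))
    if (identical_retest) {
      key <- paste(design$subject_id, design$phase, design$game, design$level)
      seeds[design$timepoint == "retest"] <-
        seeds[design$timepoint == "test"][match(key[design$timepoint == "retest"],
                                                key[design$timepoint == "test"])]
    }
    rrs <- vector("list", nrow(design))
    art <- vector("list", nrow(design))
    for (r in seq_len(nrow(design))) {
      s <- generate_rr(
        baseline_ms = latent_mrr[r], duration_s = cfg$duration_s,
        hf_amp = hf_amp[r], lf_amp = cfg$lf_amp,
        trend_amp = cfg$trend_amp, noise_sd = cfg$noise_sd,
        resp_freq = cfg$resp_freq, seed = seeds[r]
      )
      if (cfg$artifact_rate > 0) {
        inj <- inject_artifacts(s, cfg$artifact_rate, seed = seeds[r] %% 1e6)
        s <- inj$series
        art[[r]] <- inj$truth
      } else {
        art[[r]] <- tibble::tibble(kind = character(), beat = integer())
      }
      rrs[[r]] <- s
    }
    truth$artifacts <- art
    sessions <- dplyr::bind_cols(design, tlx)
    sessions$rr <- rrs
    sessions$quality_pass <- NA
  } else {
    sessions <- dplyr::bind_cols(design, tlx)
    sessions$mrr_ms <- latent_mrr
    sessions$mean_hr_bpm <- 60000 / latent_mrr
    # latent stand-ins for the oscillation-driven metrics: amplitude-scaled
    # with occasion noise sharing the mRR variance split
    rms_lat <- hf_amp * sqrt(2) *
      abs(sin(pi * cfg$resp_freq * latent_mrr / 1000))
    sessions$rmssd_ms <- rms_lat
    sessions$sd1_ms <- rms_lat / sqrt(2)
    sessions$hf_ms2 <- hf_amp^2 / 2
    sessions$hf_nu <- NA_real_
    sessions$pns_index <- NA_real_
    sessions$quality_pass <- TRUE
  }

  structure(list(sessions = tibble::as_tibble(sessions), truth = truth,
                 config = cfg),
            class = "hrv_cohort")
}

generate_tlx <- function(level, tlx_base) {
  n <- length(level)
  base <- tlx_base[level]
  draw <- function() {
    pmin(20L, pmax(0L, as.integer(round(stats::rnorm(n, base, 3)))))
  }
  out <- tibble::tibble(
    tlx_effort = draw(), tlx_mental = draw(), tlx_temporal = draw(),
    tlx_physical = draw(), tlx_performance = draw(), tlx_frustration = draw()
  )
  out
}

#' @export
print.hrv_cohort <- function(x, ...) {
  cat(sprintf(
    "<hrv_cohort: %d subjects x %d games x %d levels x 2 timepoints (%d sessions)%s>\n",
    x$config$n_subjects, length(x$config$games), length(x$config$levels),
    nrow(x$sessions), if ("rr" %in% names(x$sessions)) " with signals" else ""
  ))
  invisible(x)
}
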