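test_that("generate_rr honours its degenerate and oracle cases", {
  # no modulation, no noise: constant at baseline
  s <- generate_rr(900, 60, hf_amp = 0, lf_amp = 0, trend_amp = 0,
                   noise_sd = 0, seed = 81)
  expect_true(all(abs(s$rr_ms - 900) < 1e-9))
  expect_gte(rr_duration(s), 60)

  # configured amplitudes that could go non-positive are rejected
  expect_error(generate_rr(100, 60, hf_amp = 80, lf_amp = 40),
               class = "vmhrv_error_argument")

  # determinism under a fixed seed
  a <- generate_rr(900, 90, hf_amp = 30, noise_sd = 10, seed = 82)
  b <- generate_rr(900, 90, hf_amp = 30, noise_sd = 10, seed = 82)
  expect_identical(a$rr_ms, b$rr_ms)
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  cfg <- cohort_config(n_subjects = 4, games = "Simple", seed = 83)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truth$true_mrr_ms, c2$truth$true_mrr_ms)
  expect_identical(
    purrr::map(c1$sessions$rr, "rr_ms"),
    purrr::map(c2$sessions$rr, "rr_ms")
  )
  expect_identical(c1$sessions$tlx_effort, c2$sessions$tlx_effort)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(true_icc = 0), class = "vmhrv_error_argument")
  expect_error(cohort_config(artifact_rate = 0.6),
               class = "vmhrv_error_argument")
  expect_error(
    cohort_config(level_effect_rr = c(easy = 0, challenging = 20,
                                      excessive = -50)),
    class = "vmhrv_error_argument"
  )
  expect_error(
    cohort_config(baseline_rr_mean = 300, baseline_rr_sd = 90),
    class = "vmhrv_error_argument"
  )
})

test_that("the variance split reproduces the target ICC analytically", {
  # latent mode: occasion noise sd = sigma_b * sqrt(1/icc - 1)
  cfg <- cohort_config(n_subjects = 500, games = "Simple", true_icc = 0.75,
                       seed = 84)
  coh <- generate_cohort(cfg, signals = FALSE)
  wide <- coh$sessions |>
    dplyr::filter(.data$level == "easy") |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "timepoint",
                       values_from = "mrr_ms")
  ic <- icc31(cbind(wide$test, wide$retest))
  expect_equal(ic$icc, 0.75, tolerance = 0.07)

  # true_icc = 1 collapses the occasion noise entirely
  cfg1 <- cohort_config(n_subjects = 20, games = "Simple", true_icc = 1,
                        seed = 85)
  coh1 <- generate_cohort(cfg1, signals = FALSE)
  wide1 <- coh1$sessions |>
    dplyr::filter(.data$level == "challenging") |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "timepoint",
                       values_from = "mrr_ms")
  expect_equal(wide1$test, wide1$retest)
})

test_that("level effects order the generated condition means", {
  cfg <- cohort_config(n_subjects = 30, games = "Simple", noise_sd = 10,
                       seed = 86)
  coh <- generate_cohort(cfg, signals = FALSE)
  means <- coh$sessions |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(m = mean(.data$mrr_ms)) |>
    dplyr::arrange(match(.data$level, analysis_levels()))
  expect_true(means$m[1] > means$m[2] && means$m[2] > means$m[3])

  # analytic moment match: each condition mean within 3 SEM of its target
  per_level <- coh$sessions |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(m = mean(.data$mrr_ms), se = sd(.data$mrr_ms) /
                       sqrt(dplyr::n()))
  target <- cfg$baseline_rr_mean + cfg$level_effect_rr[per_level$level]
  expect_true(all(abs(per_level$m - target) < 3 * per_level$se))
})

test_that("TLX subscores rise with demand and stay in range", {
  cfg <- cohort_config(n_subjects = 60, games = "Simple", seed = 87)
  coh <- generate_cohort(cfg, signals = FALSE)
  tlx <- coh$sessions |>
    dplyr::mutate(total = rtlx(dplyr::pick(dplyr::starts_with("tlx_")))) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(m = mean(.data$total)) |>
    dplyr::arrange(match(.data$level, analysis_levels()))
  expect_true(all(diff(tlx$m) > 0))
  sub <- as.matrix(coh$sessions[, vmhrv:::session_tlx_cols])
  expect_true(all(sub >= 0 & sub <= 20))
})

test_that("artifact injection matches its contract", {
  s <- generate_rr(900, 200, hf_amp = 25, lf_amp = 15, trend_amp = 15,
                   noise_sd = 5, seed = 88)

  # rate 0 is the identity
  out0 <- inject_artifacts(s, 0)
  expect_identical(out0$series$rr_ms, s$rr_ms)
  expect_equal(nrow(out0$truth), 0L)

  # duration is preserved by construction for every kind
  for (kind in c("missed", "extra", "ectopic")) {
    out <- inject_artifacts(s, 0.04, kinds = kind, seed = 89)
    expect_equal(rr_duration(out$series), rr_duration(s), tolerance = 1e-9)
    expect_gt(nrow(out$truth), 0L)
  }
  expect_error(inject_artifacts(s, 0.5), class = "vmhrv_error_argument")
})

test_that("injected artifacts are recovered at high sensitivity", {
  hits <- unlist(purrr::map(c(90, 91, 92), function(seed) {
    s <- generate_rr(900, 300, hf_amp = 25, lf_amp = 15, trend_amp = 15,
                     noise_sd = 5, seed = seed)
    inj <- inject_artifacts(s, 0.03, kinds = c("missed", "extra"),
                            seed = seed + 10)
    rep <- detect_artifacts(inj$series)
    flagged <- which(rep$labels != "normal")
    vapply(inj$truth$beat, function(b) any(abs(flagged - b) <= 1), logical(1))
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("heavy artifact contamination trips the downstream gate", {
  fails <- purrr::map_lgl(1:8, function(i) {
    s <- generate_rr(900, 120, hf_amp = 25, lf_amp = 15, trend_amp = 15,
                     noise_sd = 5, seed = 100 + i)
    inj <- inject_artifacts(s, 0.06, seed = 200 + i)
    !quality_gate(detect_artifacts(inj$series))
  })
  expect_gte(mean(fails), 0.75)
})
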