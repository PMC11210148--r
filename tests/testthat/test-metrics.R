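test_that("time-domain metrics match hand arithmetic", {
  v <- c(800, 810, 790, 800)
  expect_equal(mean_rr(v), 800)
  expect_equal(mean_hr(v), 75)
  expect_equal(rmssd(v), sqrt((100 + 400 + 100) / 3))
  expect_equal(rmssd(c(800, 820)), 20)
  expect_equal(poincare_sd1(c(800, 820)), 20 / sqrt(2))
  expect_equal(mean_rr(750), 750)
  expect_equal(rmssd(rep(1000, 50)), 0)
  expect_error(mean_rr(numeric(0)), class = "vmhrv_error_insufficient_data")
  expect_error(rmssd(1000), class = "vmhrv_error_insufficient_data")
})

test_that("SD1 equals RMSSD / sqrt(2) for arbitrary inputs", {
  set.seed(31)
  for (i in 1:25) {
    v <- runif(sample(5:200, 1), 500, 1200)
    expect_equal(poincare_sd1(v), rmssd(v) / sqrt(2))
  }
})

test_that("RMSSD is shift-invariant while mean RR shifts exactly", {
  set.seed(32)
  v <- runif(100, 700, 1000)
  expect_equal(rmssd(v + 150), rmssd(v))
  expect_equal(mean_rr(v + 150), mean_rr(v) + 150)
})

test_that("pns_index standardizes against the normals", {
  nm <- pns_normals(mrr_mean = 900, mrr_sd = 100, rmssd_mean = 40,
                    rmssd_sd = 20, sd1nu_mean = 0.3, sd1nu_sd = 0.1)
  # all components at the normative means
  expect_equal(pns_index(900, 40, 30, 70, nm), 0)
  # each component one normative SD above its mean: sd1nu = 0.4 needs
  # sd1 / (sd1 + sd2) = 0.4
  expect_equal(pns_index(1000, 60, 40, 60, nm), 1)
  # mRR one SD below, others at their means
  expect_equal(pns_index(800, 40, 30, 70, nm), -1 / 3)
  expect_error(pns_index(900, 40, 0, 0, nm),
               class = "vmhrv_error_undefined_metric")
})

test_that("pns_index is strictly increasing in each component", {
  nm <- pns_normals()
  base <- pns_index(900, 40, 30, 70, nm)
  expect_gt(pns_index(950, 40, 30, 70, nm), base)
  expect_gt(pns_index(900, 50, 30, 70, nm), base)
  # raising sd1 at fixed sd2 raises sd1nu
  expect_gt(pns_index(900, 40, 35, 70, nm), base)
})

test_that("stronger respiratory modulation raises HF power and RMSSD", {
  amps <- c(10, 25, 45)
  res <- vapply(amps, function(A) {
    s <- generate_rr(1000, 180, hf_amp = A, lf_amp = 0, trend_amp = 0,
                     noise_sd = 0, seed = 33)
    tach <- detrend_sp(s)
    c(rmssd(tach), band_powers(psd_welch(tach))$hf)
  }, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) > 0))
})

test_that("compute_hrv handles a degenerate constant recording", {
  out <- compute_hrv(rr_series(rep(1000, 320)))
  expect_equal(out$mrr_ms, 1000)
  expect_equal(out$mean_hr_bpm, 60)
  expect_equal(out$rmssd_ms, 0, tolerance = 1e-6)
  expect_equal(out$sd1_ms, 0, tolerance = 1e-6)
  expect_equal(out$hf_ms2, 0, tolerance = 1e-6)
  expect_true(out$quality_pass)
})

test_that("segments failing the quality gate become missing records", {
  s <- generate_rr(900, 120, hf_amp = 30, lf_amp = 20, trend_amp = 20,
                   noise_sd = 8, seed = 34)
  inj <- inject_artifacts(s, 0.10, seed = 35)
  out <- compute_hrv(inj$series)
  expect_false(out$quality_pass)
  expect_true(is.na(out$mrr_ms))
  expect_match(out$fail_reason, "quality gate")
})

test_that("compute_hrv recovers generator ground truth on a resting-like fixture", {
  s <- generate_rr(950, 300, hf_amp = 40, lf_amp = 20, trend_amp = 25,
                   noise_sd = 6, seed = 36)
  out <- compute_hrv(s)
  expect_true(out$quality_pass)
  expect_equal(out$mrr_ms, 950, tolerance = 0.02)
  expect_equal(out$hf_ms2, 40^2 / 2, tolerance = 0.25)
  expect_equal(out$sd1_ms, out$rmssd_ms / sqrt(2))
  expect_gte(out$hf_nu, 0)
  expect_lte(out$hf_nu, 1)
})
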