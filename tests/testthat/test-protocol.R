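test_that("age-predicted HRmax follows 208 - 0.7 * age", {
  expect_equal(age_predicted_hrmax(60), 166)
  expect_equal(age_predicted_hrmax(67), 161.1)
  expect_error(age_predicted_hrmax(0), class = "vmhrv_error_argument")
  expect_error(age_predicted_hrmax(130), class = "vmhrv_error_argument")
})

test_that("Karvonen target interpolates the heart-rate reserve", {
  expect_equal(karvonen_target(60, 161.1, 0.40), 100.44)
  expect_equal(karvonen_target(60, 160, 0), 60)
  expect_equal(karvonen_target(60, 160, 1), 160)
  expect_error(karvonen_target(160, 120), class = "vmhrv_error_argument")
})

test_that("Karvonen target is strictly increasing and bounded by rest/max", {
  fr <- seq(0.05, 0.95, by = 0.15)
  targets <- vapply(fr, function(f) karvonen_target(62, 158, f), numeric(1))
  expect_true(all(diff(targets) > 0))
  expect_true(all(targets > 62 & targets < 158))
})

test_that("ramp test returns the first stage whose 20-s average meets target", {
  cfg <- ramp_config()
  # deterministic stream: stage averages 90, 95, 100, ...
  stream <- tibble::tibble(
    time_s = seq(0, 200 - 1),
    hr_bpm = 90 + 5 * (seq(0, 199) %/% 20)
  )
  expect_equal(ramp_test(stream, hr_target = 100, cfg), 90) # third stage
  expect_equal(ramp_test(stream, hr_target = 50, cfg), 80)  # immediate
  expect_error(ramp_test(stream, hr_target = 500, cfg),
               class = "vmhrv_error_not_reached")
  err <- tryCatch(ramp_test(stream, hr_target = 500, cfg), error = identity)
  expect_equal(err$last_stage_spm, 125)
})

test_that("ramp output always sits on the cadence grid", {
  cfg <- ramp_config()
  for (seed in 1:5) {
    stream <- simulate_hr_ramp(hr_start = 70, rise_bpm_per_stage = 4,
                               n_stages = 25, noise_sd = 2, seed = seed)
    spm <- ramp_test(stream, hr_target = 100, cfg)
    expect_equal((spm - cfg$start_spm) %% cfg$increment_spm, 0)
  }
})

test_that("resting HR stability band is inclusive at +/- 5 bpm", {
  expect_true(hr_rest_stable(64, 60))
  expect_true(hr_rest_stable(65, 60))
  expect_false(hr_rest_stable(66, 60))
  expect_true(hr_rest_stable(55, 60))
})

test_that("raw TLX is the unweighted subscale sum", {
  expect_equal(rtlx(5, 10, 3, 7, 2, 4), 31)
  expect_equal(rtlx(20, 20, 20, 20, 20, 20), 120)
  expect_equal(rtlx(0, 0, 0, 0, 0, 0), 0)
  expect_error(rtlx(21, 0, 0, 0, 0, 0), class = "vmhrv_error_validation")
  expect_error(rtlx(-1, 0, 0, 0, 0, 0), class = "vmhrv_error_validation")
})

test_that("rtlx is permutation-invariant over subscales and vectorized", {
  scores <- c(5, 10, 3, 7, 2, 4)
  perms <- replicate(10, sample(scores), simplify = FALSE)
  for (p in perms) {
    expect_equal(do.call(rtlx, as.list(p)), 31)
  }
  df <- tibble::tibble(
    tlx_effort = c(5, 20), tlx_mental = c(10, 20), tlx_temporal = c(3, 20),
    tlx_physical = c(7, 20), tlx_performance = c(2, 20),
    tlx_frustration = c(4, 20)
  )
  expect_equal(rtlx(df), c(31, 120))
})

test_that("reactivity is the on-task minus rest difference with NA propagation", {
  rest <- compute_hrv(generate_rr(1000, 300, hf_amp = 40, noise_sd = 5,
                                  seed = 41))
  task <- compute_hrv(generate_rr(800, 120, hf_amp = 20, noise_sd = 5,
                                  seed = 42))
  d <- hrv_reactivity(task, rest)
  expect_equal(d$mrr_ms, task$mrr_ms - rest$mrr_ms)
  expect_lt(d$mrr_ms, 0) # faster heart rate on task

  expect_equal(hrv_reactivity(task, task)$rmssd_ms, 0)

  task_na <- task
  task_na$hf_ms2 <- NA_real_
  expect_true(is.na(hrv_reactivity(task_na, rest)$hf_ms2))
})
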