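test_that("the eligibility gate needs fair reliability at all three levels", {
  expect_true(eligibility_gate(c(0.6, 0.7, 0.8)))
  expect_false(eligibility_gate(c(0.6, 0.49, 0.8)))
  expect_true(eligibility_gate(c(0.5, 0.5, 0.5))) # inclusive boundary
  expect_false(eligibility_gate(c(0.6, NA, 0.8)))
  expect_false(eligibility_gate(c(0.6, 0.8)))
})

test_that("effect size r and its bands follow the printed conventions", {
  expect_equal(effect_size_r(0, 20), 0)
  expect_equal(effect_size_r(2, 16), 0.5)
  expect_equal(effect_size_r(-2, 16), 0.5)
  expect_equal(classify_r(c(0.05, 0.1, 0.29, 0.3, 0.4, 0.49, 0.5, 0.95, 1.2)),
               c("negligible", "small", "small", "medium", "medium", "medium",
                 "large", "large", "large"))
  expect_error(classify_r(-0.1), class = "vmhrv_error_argument")
})

test_that("Bonferroni correction is exact for the three level pairs", {
  set.seed(71)
  df <- tidyr::expand_grid(subject = sprintf("s%d", 1:15),
                           level = analysis_levels()) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  pw <- posthoc_pairwise(df, "parametric")
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p_raw))
})

test_that("identical level distributions yield near-1 adjusted p-values", {
  set.seed(72)
  v <- rnorm(18, 900, 40)
  df <- tidyr::expand_grid(subject = sprintf("s%d", 1:18),
                           level = analysis_levels()) |>
    dplyr::mutate(value = rep(v, each = 3)) # identical across levels
  pw <- posthoc_pairwise(df, "nonparametric")
  expect_true(all(pw$p_adj == 1))
  expect_true(all(pw$r == 0))
})

test_that("a subject-constant shift gives tiny p-values and large r", {
  set.seed(73)
  base <- rnorm(20, 900, 50)
  df <- dplyr::bind_rows(
    tibble::tibble(subject = sprintf("s%d", 1:20), level = "easy",
                   value = base),
    tibble::tibble(subject = sprintf("s%d", 1:20), level = "challenging",
                   value = base - 60 + rnorm(20, 0, 5)),
    tibble::tibble(subject = sprintf("s%d", 1:20), level = "excessive",
                   value = base - 120 + rnorm(20, 0, 5))
  )
  for (branch in c("parametric", "nonparametric")) {
    pw <- posthoc_pairwise(df, branch)
    expect_true(all(pw$p_adj < 0.001))
    expect_true(all(pw$r > 0.5))
    expect_true(all(pw$r_band == "large"))
  }
})

test_that("the signed-rank engine agrees with stats::wilcox.test", {
  set.seed(74)
  for (i in 1:10) {
    n <- sample(6:24, 1)
    x <- rnorm(n, 0, 3)
    y <- x + rnorm(n, 0.8, 2)
    ours <- vmhrv:::signed_rank(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                               exact = TRUE))
    if (!any(duplicated(abs(x - y))) && all(x != y)) {
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
  }
  # large-sample branch tracks the corrected normal approximation
  x <- rnorm(60)
  y <- x + rnorm(60, 0.3)
  ours <- vmhrv:::signed_rank(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("zero differences are dropped and counted", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1, 2, 3, 5, 7, 9)
  out <- vmhrv:::signed_rank(x, y)
  expect_equal(out$n_zero, 3L)
  expect_equal(out$n_used, 3L)
})

test_that("validity_test refuses and never computes post-hocs when gated", {
  set.seed(75)
  d <- null_design(12)
  # reliability gate failure
  res <- validity_test(d, level_iccs = c(0.8, 0.45, 0.7))
  expect_false(res$eligible)
  expect_equal(nrow(res$pairwise[[1]]), 0L)
  expect_match(res$gate_reason, "reliability gate")

  # eligible but no level effect -> refused with the ANOVA reason
  res2 <- validity_test(d, level_iccs = c(0.8, 0.8, 0.8))
  if (res2$p_level > 0.05) {
    expect_equal(nrow(res2$pairwise[[1]]), 0L)
    expect_match(res2$gate_reason, "not significant")
  }
})

test_that("a real level effect passes the gate end-to-end", {
  set.seed(76)
  n <- 20
  X <- matrix(rnorm(n * 6, 0, 0.5), n, 6) + rnorm(n)
  X <- X + matrix(rep(c(0, -1.5, -3), 2), n, 6, byrow = TRUE)
  d <- long_design(X)
  res <- validity_test(d, level_iccs = c(0.9, 0.9, 0.9))
  expect_true(res$eligible)
  expect_lt(res$p_level, 0.05)
  pw <- res$pairwise[[1]]
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$p_adj < 0.05))
})
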