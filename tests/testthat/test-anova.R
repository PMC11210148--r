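test_that("the within-subject decomposition matches stats::aov", {
  set.seed(61)
  d <- null_design(12)
  d$value <- d$value + ifelse(d$level == "excessive", 0.8, 0)
  ours <- rm_anova_2way(d)
  fit <- stats::aov(value ~ timepoint * level +
                      Error(subject / (timepoint * level)),
                    data = transform(d, subject = factor(subject),
                                     timepoint = factor(timepoint),
                                     level = factor(level)))
  sm <- summary(fit)
  f_aov <- c(
    timepoint = sm[["Error: subject:timepoint"]][[1]]["timepoint", "F value"],
    level = sm[["Error: subject:level"]][[1]]["level", "F value"],
    ix = sm[["Error: subject:timepoint:level"]][[1]]["timepoint:level",
                                                     "F value"]
  )
  expect_equal(ours$statistic, unname(f_aov), tolerance = 1e-10)
})

test_that("the 2-level factor never receives a sphericity correction", {
  set.seed(62)
  d <- null_design(10)
  out <- rm_anova_2way(d)
  tp <- out[out$term == "timepoint", ]
  expect_equal(tp$epsilon, 1)
  expect_false(tp$gg_applied)
  expect_true(is.na(tp$mauchly_p))
})

test_that("Greenhouse-Geisser kicks in under a sphericity violation", {
  set.seed(63)
  # build strongly non-spherical level scores: one level far noisier
  n <- 25
  base <- rnorm(n)
  lv <- cbind(base + rnorm(n, 0, 0.1), base + rnorm(n, 0, 0.1),
              base + rnorm(n, 0, 3))
  X <- cbind(lv, lv + rnorm(n, 0, 0.1)) # retest close to test
  X <- X[, c(1, 2, 3, 4, 5, 6)]
  d <- long_design(X)
  out <- rm_anova_2way(d)
  lvl <- out[out$term == "level", ]
  expect_lt(lvl$mauchly_p, 0.05)
  expect_true(lvl$gg_applied)
  expect_lt(lvl$epsilon, 1)
  expect_lt(lvl$df1, 2) # corrected df shrink below the nominal b - 1
})

test_that("unbalanced or incomplete designs are refused", {
  d <- null_design(8)
  expect_error(rm_anova_2way(d[-1, ]), class = "vmhrv_error_design")
  d2 <- d
  d2$value[3] <- NA
  expect_error(rm_anova_2way(d2), class = "vmhrv_error_design")
})

test_that("rank ATS detects a deterministic monotone level effect", {
  set.seed(64)
  n <- 20
  X <- matrix(rnorm(n * 6), n, 6) + rnorm(n)
  offs <- c(0, 1.2, 2.4) # identical monotone shift for every subject
  X <- X + matrix(rep(offs, 2), n, 6, byrow = TRUE)
  d <- long_design(X)
  out <- rank_ats_anova(d)
  p_level <- out$p.value[out$term == "level"]
  expect_lt(p_level, 0.05)
  # a within-subject permutation test agrees the effect is real
  expect_lt(perm_level_p(d, n_perm = 5000, seed = 65), 0.05)
})

test_that("rank ATS tracks the permutation oracle across effect sizes", {
  # the ATS p-value and a within-subject permutation p-value are computed
  # from different statistics, so they need not match point-wise on any
  # single draw; across a ladder of effect sizes they must move together
  # and agree on clear verdicts
  set.seed(66)
  deltas <- c(0, 0, 0.3, 0.6, 0.9, 1.5)
  p_ats <- p_perm <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    X <- matrix(rnorm(15 * 6), 15, 6) + rnorm(15) +
      matrix(rep(deltas[i] * c(0, 1, 2), 2), 15, 6, byrow = TRUE)
    d <- long_design(X)
    out <- rank_ats_anova(d)
    p_ats[i] <- out$p.value[out$term == "level"]
    p_perm[i] <- perm_level_p(d, n_perm = 1500, seed = 100 + i)
  }
  expect_gte(cor(p_ats, p_perm, method = "spearman"), 0.7)
  expect_true(all((p_ats <= 0.05) == (p_perm <= 0.05) |
                    pmin(p_ats, p_perm) > 0.01))
})

test_that("rank ATS refuses degenerate inputs", {
  d <- null_design(6)
  d$value <- 1
  expect_error(rank_ats_anova(d), class = "vmhrv_error_degenerate")
  d1 <- null_design(1)
  expect_error(rank_ats_anova(d1), class = "vmhrv_error_degenerate")
})

test_that("branch routing follows Shapiro-Wilk screening", {
  set.seed(68)
  expect_equal(route_test(rnorm(50)), "parametric")
  expect_equal(route_test(exp(rnorm(50, 0, 1.5))), "nonparametric")
  expect_equal(route_test(rep(5, 20)), "nonparametric") # SW undefined

  # per-cell routing with deterministically well-behaved cells: ideal
  # normal scores in every cell route parametric, one heavy-skew cell
  # flips the whole design
  d <- null_design(15) |>
    dplyr::group_by(.data$timepoint, .data$level) |>
    dplyr::mutate(value = sort(qnorm(ppoints(dplyr::n()))) +
                    dplyr::cur_group_id() * 10) |>
    dplyr::ungroup()
  expect_equal(route_test(d), "parametric")
  d$value[d$level == "easy"] <- exp(3 * d$value[d$level == "easy"])
  expect_equal(route_test(d), "nonparametric")
})
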