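#' Reliability gate for the validity analysis
#'
#' A metric is eligible for validity testing only when it shows at least
#' fair test-retest reliability (ICC(3,1) >= 0.5, inclusive) at *all three*
#' standardized demand levels; a missing level ICC fails the gate.
#'
#' @param iccs Numeric vector of the three per-level ICC estimates.
#' @return `TRUE` when eligible.
#' @examples
#' eligibility_gate(c(0.5, 0.5, 0.5)) # TRUE (inclusive)
#' @export
eligibility_gate <- function(iccs) {
  iccs <- unlist(iccs)
  if (length(iccs) != 3L || anyNA(iccs)) return(FALSE)
  all(iccs >= 0.5)
}

#' Effect size r from a standardized statistic
#'
#' \eqn{r = |Z| / \sqrt{N}} with `N` the number of observations entering the
#' comparison (both occasions of every pair for a paired test).
#'
#' @param z Standardized test statistic.
#' @param n_obs Number of observations in the comparison.
#' @return The effect size r.
#' @examples
#' effect_size_r(2, 16) # 0.5
#' @export
effect_size_r <- function(z, n_obs) {
  if (!is_scalar_number(n_obs) || n_obs < 1) {
    abort_argument("`n_obs` must be >= 1.")
  }
  abs(z) / sqrt(n_obs)
}

#' Interpret an effect size r
#'
#' Bands: negligible (< 0.1), small (0.1-0.3), medium (0.3-0.5), large
#' (>= 0.5). The conventional banding leaves r = 0.5 itself unassigned
#' between "medium" (< 0.5) and "large" (> 0.5); it is classified as large
#' here. Note that the t-based variant of r used in the parametric branch
#' (\eqn{r = |t| / \sqrt{n_{pairs}}}) is not bounded by 1.
#'
#' @param r Effect size(s), `>= 0`.
#' @return Character vector of bands.
#' @examples
#' classify_r(c(0.05, 0.3, 0.95))
#' @export
classify_r <- function(r) {
  if (any(r < 0, na.rm = TRUE)) abort_argument("`r` must be >= 0.")
  cut_band(r, c(0.1, 0.3, 0.5),
           c("negligible", "small", "medium", "large"))
}

#' Post-hoc pairwise demand-level comparisons
#'
#' Compares the three standardized demand levels pairwise once the omnibus
#' gate is satisfied (significant level main effect, no significant
#' interaction). Each subject contributes one value per level (the mean over
#' occasions). The parametric branch runs paired t-tests with effect size
#' \eqn{r = |t| / \sqrt{n_{pairs}}}; the nonparametric branch runs Wilcoxon
#' signed-rank tests (exact null for <= 25 non-zero pairs and no ties,
#' normal approximation with tie and continuity correction otherwise) with
#' \eqn{r = |Z| / \sqrt{N}}, `N` = observations in the comparison. Zero
#' differences are dropped, with the count reported. All p-values are
#' Bonferroni-corrected for the three comparisons (`p_adj = min(1, 3 p)`).
#'
#' @param data Data frame with columns `subject`, `level`, `value` (one
#'   value per subject and level).
#' @param branch `"parametric"` or `"nonparametric"` (from [route_test()]).
#' @return A tibble with one row per level pair: `comparison`, `n_pairs`,
#'   `n_zero_dropped`, `statistic`, `p_raw`, `p_adj`, `r`, `r_band`.
#' @export
posthoc_pairwise <- function(data, branch = c("parametric", "nonparametric")) {
  branch <- match.arg(branch)
  need <- c("subject", "level", "value")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort_argument("`data` needs columns subject, level, value.")
  }
  lv <- intersect(analysis_levels(), unique(as.character(data$level)))
  if (length(lv) < 2L) abort_argument("Need at least two demand levels.")
  prs <- utils::combn(lv, 2, simplify = FALSE)
  n_comp <- length(prs)
  rows <- purrr::map(prs, function(pr) {
    wide <- data |>
      dplyr::filter(.data$level %in% pr) |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "level",
                         values_from = "value") |>
      tidyr::drop_na()
    x <- wide[[pr[1]]]
    y <- wide[[pr[2]]]
    n_pairs <- length(x)
    if (n_pairs < 3L) {
      return(tibble::tibble(
        comparison = paste(pr, collapse = " vs "), n_pairs = n_pairs,
        n_zero_dropped = NA_integer_, statistic = NA_real_,
        p_raw = NA_real_, p_adj = NA_real_, r = NA_real_,
        r_band = NA_character_
      ))
    }
    if (branch == "parametric") {
      tt <- stats::t.test(x, y, paired = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
      r <- effect_size_r(stat, n_pairs) # t-based convention, can exceed 1
      nz <- 0L
    } else {
      wr <- signed_rank(x, y)
      stat <- wr$z
      p <- wr$p
      nz <- wr$n_zero
      r <- if (wr$n_used > 0) effect_size_r(wr$z, 2 * wr$n_used) else 0
    }
    tibble::tibble(
      comparison = paste(pr, collapse = " vs "), n_pairs = n_pairs,
      n_zero_dropped = nz, statistic = stat, p_raw = p,
      p_adj = min(1, n_comp * p), r = r, r_band = classify_r(r)
    )
  })
  dplyr::bind_rows(rows)
}

# Wilcoxon signed-rank: exact two-sided p for n <= 25 without ties, normal
# approximation with tie + continuity correction otherwise; Z always from
# the corrected normal approximation (effect-size convention)
signed_rank <- function(x, y) {
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) {
    return(list(z = 0, p = 1, n_used = 0L, n_zero = n_zero))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sig2 > 0) {
    (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
  } else {
    0
  }
  has_ties <- any(duplicated(abs(d)))
  p <- if (n <= 25L && !has_ties) {
    if (w > mu) {
      min(1, 2 * stats::psignrank(w - 1, n, lower.tail = FALSE))
    } else {
      min(1, 2 * stats::psignrank(w, n))
    }
  } else {
    min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }
  list(z = z, p = p, n_used = n, n_zero = n_zero)
}

#' Validity analysis of a metric across demand levels
#'
#' Implements the reliability-gated validity procedure for one metric and
#' one phase x game: (1) the metric must pass [eligibility_gate()] on its
#' three per-level ICCs; (2) the demand-level main effect must be
#' significant with no significant timepoint x level interaction in the
#' branch-matched omnibus test; only then (3) are the pairwise post-hoc
#' comparisons computed. Refusals carry the gate reason; post-hocs are never
#' silently computed.
#'
#' @param design Long data frame (`subject`, `timepoint`, `level`, `value`)
#'   for one phase x game.
#' @param level_iccs Numeric vector of the three per-level ICC(3,1)
#'   estimates for this metric.
#' @param alpha Significance level (default 0.05, two-sided).
#' @param branch Analysis branch; defaults to [route_test()] on the design.
#' @return A one-row tibble of class `validity_result`: `eligible`,
#'   `branch`, `statistic_level`, `p_level`, `p_interaction`, `gate_reason`,
#'   and a `pairwise` list-column holding the [posthoc_pairwise()] table
#'   (empty when refused).
#' @export
validity_test <- function(design, level_iccs, alpha = 0.05, branch = NULL) {
  if (is.null(branch)) branch <- route_test(design)
  eligible <- eligibility_gate(level_iccs)
  empty_pw <- tibble::tibble(
    comparison = character(), n_pairs = integer(),
    n_zero_dropped = integer(), statistic = numeric(), p_raw = numeric(),
    p_adj = numeric(), r = numeric(), r_band = character()
  )
  refuse <- function(reason, stat = NA_real_, p_l = NA_real_,
                     p_i = NA_real_) {
    tibble::tibble(
      eligible = eligible, branch = branch, statistic_level = stat,
      p_level = p_l, p_interaction = p_i, gate_reason = reason,
      pairwise = list(empty_pw)
    )
  }
  if (!eligible) {
    return(refuse("reliability gate: ICC(3,1) < 0.5 (or missing) in at least one level"))
  }
  om <- if (branch == "parametric") {
    rm_anova_2way(design)
  } else {
    rank_ats_anova(design)
  }
  stat_l <- om$statistic[om$term == "level"]
  p_l <- om$p.value[om$term == "level"]
  p_i <- om$p.value[om$term == "timepoint:level"]
  if (is.na(p_l) || p_l > alpha) {
    return(refuse("main effect of level not significant: no post-hoc comparisons",
                  stat_l, p_l, p_i))
  }
  if (!is.na(p_i) && p_i <= alpha) {
    return(refuse("significant timepoint x level interaction: no post-hoc comparisons",
                  stat_l, p_l, p_i))
  }
  subj_level <- design |>
    dplyr::group_by(.data$subject, .data$level) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  pw <- posthoc_pairwise(subj_level, branch = branch)
  tibble::tibble(
    eligible = TRUE, branch = branch, statistic_level = stat_l,
    p_level = p_l, p_interaction = p_i, gate_reason = NA_character_,
    pairwise = list(pw)
  )
}
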