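#' Two-way repeated-measures ANOVA (timepoint x demand level)
#'
#' Balanced fully-within-subject decomposition for the test-retest design:
#' factor `timepoint` (2 levels) and factor `level` (3 demand levels), each
#' tested against its own subject-interaction error stratum. Sphericity of
#' the multi-level factor and of the interaction is assessed with Mauchly's
#' test on the respective contrast covariances; when a Mauchly p-value is at
#' or below `sphericity_alpha`, the Greenhouse-Geisser epsilon scales that
#' term's degrees of freedom. The 2-level factor needs no correction
#' (sphericity is vacuous at k = 2, epsilon = 1).
#'
#' @param data Long-format data frame with columns `subject`, `timepoint`,
#'   `level` and `value`; every subject must have one value per cell.
#' @param sphericity_alpha Mauchly significance threshold triggering the
#'   correction (default 0.05).
#' @return A tibble of class `rm_anova` with one row per term (`timepoint`,
#'   `level`, `timepoint:level`): `statistic` (F), `df1`, `df2`, `epsilon`,
#'   `mauchly_p` and `p.value` (Greenhouse-Geisser corrected where
#'   triggered).
#' @export
rm_anova_2way <- function(data, sphericity_alpha = 0.05) {
  d <- as_within_design(data)
  X <- d$X # n x (a*b), cells ordered time-major: (t1,l1),(t1,l2),...
  n <- nrow(X)
  a <- d$a
  b <- d$b
  if (n < 3L) abort_insufficient("Within-subject ANOVA needs >= 3 subjects.")

  cell <- array(X, dim = c(n, b, a)) # [subject, level, time]
  g <- mean(X)
  m_t <- apply(cell, 3, mean)
  m_l <- apply(cell, 2, mean)
  m_tl <- apply(cell, c(2, 3), mean) # level x time
  m_s <- rowMeans(X)
  m_st <- apply(cell, c(1, 3), mean) # subject x time
  m_sl <- apply(cell, c(1, 2), mean) # subject x level

  ss_t <- n * b * sum((m_t - g)^2)
  ss_l <- n * a * sum((m_l - g)^2)
  ss_tl <- n * sum((t(m_tl) - outer(m_t, m_l, "+") + g)^2)
  ss_st <- b * sum((m_st - outer(m_s, m_t, "+") + g)^2)
  ss_sl <- a * sum((m_sl - outer(m_s, m_l, "+") + g)^2)
  ss_tot <- sum((X - g)^2)
  ss_s <- a * b * sum((m_s - g)^2)
  ss_stl <- ss_tot - ss_s - ss_t - ss_l - ss_tl - ss_st - ss_sl

  df <- list(t = a - 1, l = b - 1, tl = (a - 1) * (b - 1))
  dfe <- list(t = (a - 1) * (n - 1), l = (b - 1) * (n - 1),
              tl = (a - 1) * (b - 1) * (n - 1))
  Fv <- c(
    timepoint = (ss_t / df$t) / (ss_st / dfe$t),
    level = (ss_l / df$l) / (ss_sl / dfe$l),
    `timepoint:level` = (ss_tl / df$tl) / (ss_stl / dfe$tl)
  )

  # sphericity: level factor on the time-averaged data, interaction on the
  # per-level time differences (orthonormal contrasts in both cases)
  sph_l <- sphericity_stats(m_sl)
  d_lt <- cell[, , a] - cell[, , 1] # a = 2 in this design
  sph_tl <- if (a == 2L) sphericity_stats(d_lt) else sphericity_stats(m_sl)

  eps <- c(1, sph_l$epsilon, sph_tl$epsilon)
  mau <- c(NA_real_, sph_l$mauchly_p, sph_tl$mauchly_p)
  use_gg <- c(FALSE,
              !is.na(mau[2]) && mau[2] <= sphericity_alpha,
              !is.na(mau[3]) && mau[3] <= sphericity_alpha)

  df1 <- unlist(df)
  df2 <- unlist(dfe)
  adj1 <- ifelse(use_gg, eps * df1, df1)
  adj2 <- ifelse(use_gg, eps * df2, df2)
  p <- stats::pf(Fv, adj1, adj2, lower.tail = FALSE)

  structure(
    tibble::tibble(
      term = names(Fv), statistic = unname(Fv),
      df1 = unname(adj1), df2 = unname(adj2),
      epsilon = unname(eps), mauchly_p = unname(mau),
      gg_applied = unname(use_gg), p.value = unname(p)
    ),
    n = n, class = c("rm_anova", class(tibble::tibble()))
  )
}

# Mauchly's W and Greenhouse-Geisser epsilon from an n x p matrix of
# within-subject scores (p >= 2): both computed on orthonormal contrasts
sphericity_stats <- function(m) {
  n <- nrow(m)
  p <- ncol(m)
  if (p < 3L) return(list(epsilon = 1, mauchly_p = NA_real_))
  C <- orthonormal_contrasts(p)
  S <- C %*% stats::cov(m) %*% t(C)
  q <- p - 1
  tr <- sum(diag(S))
  if (tr <= 0) return(list(epsilon = 1, mauchly_p = NA_real_))
  eps <- tr^2 / (q * sum(S^2))
  detS <- det(S)
  W <- if (detS <= 0) 0 else detS / (tr / q)^q
  if (W <= 0) {
    pval <- 0
  } else {
    f <- 1 - (2 * q^2 + q + 2) / (6 * q * (n - 1))
    chi2 <- -f * (n - 1) * log(W)
    dfw <- q * (q + 1) / 2 - 1
    pval <- stats::pchisq(chi2, dfw, lower.tail = FALSE)
  }
  list(epsilon = eps, mauchly_p = pval)
}

orthonormal_contrasts <- function(p) {
  C <- stats::contr.helmert(p)
  t(C) / sqrt(colSums(C^2))
}

#' Rank-based ANOVA-type statistic for the two-within-factor design
#'
#' Robust alternative to [rm_anova_2way()] for data violating parametric
#' assumptions: all observations are mid-ranked jointly, and the
#' ANOVA-type statistic (ATS) is formed from the projected cell mean ranks
#' with the Box-type degrees-of-freedom approximation, using the empirical
#' covariance of the subject rank vectors. One-degree-of-freedom hypotheses
#' (the 2-level timepoint factor) are referred to `F(f, n - 1)` (a squared
#' rank paired-t), multi-level hypotheses to `F(f, Inf)`.
#'
#' @inheritParams rm_anova_2way
#' @return A tibble of class `rank_ats` with one row per term: `statistic`
#'   (ATS), `df1`, `df2`, `p.value`, plus the relative marginal effects as
#'   an attribute.
#' @export
rank_ats_anova <- function(data) {
  d <- as_within_design(data)
  X <- d$X
  n <- nrow(X)
  a <- d$a
  b <- d$b
  if (n < 2L) {
    abort_vmhrv("Rank ATS needs at least 2 subjects.",
                "vmhrv_error_degenerate")
  }
  if (length(unique(as.vector(X))) == 1L) {
    abort_vmhrv("All values tied: ranks are degenerate.",
                "vmhrv_error_degenerate")
  }
  R <- matrix(rank(X), n, a * b) # joint mid-ranks
  rbar <- colMeans(R)
  S <- stats::cov(R)
  Pa <- diag(a) - 1 / a
  Pb <- diag(b) - 1 / b
  Ja <- matrix(1 / a, a, a)
  Jb <- matrix(1 / b, b, b)
  Ts <- list(
    timepoint = kronecker(Pa, Jb),
    level = kronecker(Ja, Pb),
    `timepoint:level` = kronecker(Pa, Pb)
  )
  hyp_k <- c(a, b, a * b)
  rows <- purrr::map2(Ts, hyp_k, function(Tm, kk) {
    tv <- sum(diag(Tm %*% S))
    if (tv <= 0) {
      return(tibble::tibble(statistic = NA_real_, df1 = NA_real_,
                            df2 = NA_real_, p.value = NA_real_))
    }
    stat <- n * drop(t(rbar) %*% Tm %*% rbar) / tv
    f <- tv^2 / sum(diag(Tm %*% S %*% Tm %*% S))
    df2 <- if (kk == 2L) n - 1 else Inf
    tibble::tibble(statistic = stat, df1 = f, df2 = df2,
                   p.value = stats::pf(stat, f, df2, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows, .id = "term")
  rel <- (rbar - 0.5) / (n * a * b) # relative treatment effects per cell
  structure(out, relative_effects = rel, n = n,
            class = c("rank_ats", class(tibble::tibble())))
}

# validate + pivot the long design into an n x (a*b) matrix, cells ordered
# timepoint-major then level
as_within_design <- function(data) {
  need <- c("subject", "timepoint", "level", "value")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort_argument("Design needs columns subject, timepoint, level, value.")
  }
  tp <- unique(as.character(data$timepoint))
  lv <- unique(as.character(data$level))
  lv <- if (all(analysis_levels() %in% lv)) {
    intersect(analysis_levels(), lv)
  } else {
    sort(lv)
  }
  tp <- sort(tp)
  a <- length(tp)
  b <- length(lv)
  subjects <- unique(data$subject)
  n <- length(subjects)
  counts <- table(data$subject, data$timepoint, data$level)
  if (any(counts != 1L) || anyNA(data$value)) {
    abort_vmhrv(
      "Design must be balanced and complete: one value per subject x timepoint x level.",
      "vmhrv_error_design")
  }
  X <- matrix(NA_real_, n, a * b)
  for (i in seq_len(a)) {
    for (j in seq_len(b)) {
      sel <- data$timepoint == tp[i] & data$level == lv[j]
      sub <- data[sel, ]
      X[match(sub$subject, subjects), (i - 1) * b + j] <- sub$value
    }
  }
  list(X = X, a = a, b = b, timepoints = tp, levels = lv,
       subjects = subjects)
}

#' Choose the parametric or nonparametric analysis branch
#'
#' Shapiro-Wilk normality screening per design cell: if any cell's p-value
#' is at or below `alpha` (or a cell is constant, where the test is
#' undefined), the nonparametric branch is selected and medians (IQR) become
#' the reporting convention; otherwise the parametric branch with mean +/-
#' SD applies.
#'
#' @param data Either a numeric vector (one cell) or a long data frame with
#'   a `value` column and grouping columns.
#' @param alpha Normality rejection threshold (default 0.05).
#' @param group_cols Columns defining cells when `data` is a data frame.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
route_test <- function(data, alpha = 0.05,
                       group_cols = c("timepoint", "level")) {
  cells <- if (is.numeric(data)) {
    list(data)
  } else {
    if (!"value" %in% names(data)) {
      abort_argument("`data` needs a `value` column.")
    }
    gc <- intersect(group_cols, names(data))
    if (length(gc)) {
      unname(split(data$value, data[gc], drop = TRUE))
    } else {
      list(data$value)
    }
  }
  normal_ok <- vapply(cells, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || length(unique(v)) == 1L) return(FALSE)
    p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
    p > alpha
  }, logical(1))
  if (all(normal_ok)) "parametric" else "nonparametric"
}
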