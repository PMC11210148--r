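# Independent oracles, written as plain double-loop / enumeration code so
# they share no machinery with the implementation they check.

# brute-force two-way mean squares -> consistency ICC, expanded sums
oracle_icc31 <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) {
    ri <- sum(m[i, ]) / k
    ss_rows <- ss_rows + k * (ri - grand)^2
  }
  ss_cols <- 0
  for (j in seq_len(k)) {
    cj <- sum(m[, j]) / n
    ss_cols <- ss_cols + n * (cj - grand)^2
  }
  ss_tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_tot <- ss_tot + (m[i, j] - grand)^2
    }
  }
  ms_rows <- ss_rows / (n - 1)
  ms_err <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

# exhaustive scan oracle for long/short intervals against a local median
oracle_scan_artifacts <- function(rr, win = 11) {
  n <- length(rr)
  flags <- rep(FALSE, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - win %/% 2)
    hi <- min(n, i + win %/% 2)
    med <- median(rr[lo:hi])
    if (rr[i] > 1.5 * med || rr[i] < 0.5 * med) flags[i] <- TRUE
  }
  which(flags)
}

# within-subject permutation test for a level effect: permute level labels
# within each subject x timepoint block, re-rank, recompute the projected
# rank statistic
perm_level_p <- function(design, n_perm = 5000, seed = 1) {
  set.seed(seed)
  stat_of <- function(d) {
    tab <- tapply(rank(d$value), list(d$timepoint, d$level), mean)
    lm <- colMeans(tab)
    sum((lm - mean(lm))^2)
  }
  obs <- stat_of(design)
  key <- paste(design$subject, design$timepoint)
  hits <- 0
  for (b in seq_len(n_perm)) {
    perm <- design
    for (kk in unique(key)) {
      idx <- which(key == kk)
      perm$level[idx] <- sample(design$level[idx])
    }
    if (stat_of(perm) >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# dense direct solve of the penalized least-squares detrend (no sparsity)
oracle_sp_trend <- function(z, lambda) {
  m <- length(z)
  D <- matrix(0, m - 2, m)
  for (r in seq_len(m - 2)) {
    D[r, r] <- 1
    D[r, r + 1] <- -2
    D[r, r + 2] <- 1
  }
  solve(diag(m) + lambda^2 * t(D) %*% D, z)
}

# small helper: long 2x3 within design from an n x 6 matrix (time-major)
long_design <- function(X) {
  n <- nrow(X)
  tidyr::expand_grid(
    subject = sprintf("s%02d", seq_len(n)),
    timepoint = c("test", "retest"),
    level = c("easy", "challenging", "excessive")
  ) |>
    dplyr::mutate(value = as.vector(t(X)))
}

# null 2x3 within-subject data: subject effect + iid noise
null_design <- function(n = 20) {
  X <- matrix(rnorm(n * 6), n, 6) + rnorm(n)
  long_design(X)
}
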