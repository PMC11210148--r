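#' Analyze a cohort end-to-end
#'
#' Runs the full pipeline over a cohort: per-recording artifact correction,
#' quality gating, windowing (the trailing `window_s` of on-task trials),
#' vm-HRV metric computation, then the test-retest reliability grid and
#' reliability-gated validity analysis per metric. Excluded recordings are
#' collected with machine-readable reasons, never imputed.
#'
#' @param cohort An `hrv_cohort` from [generate_cohort()], a cohort
#'   directory written by [write_cohort()], or a session table whose metric
#'   columns are already filled.
#' @param metrics Metric columns to analyze (default mRR, RMSSD, HF, HFnu,
#'   SD1, PNS index).
#' @param window_s Trailing on-task analysis window in seconds (default 60).
#' @param cfg,bands,normals,threshold_scale,gate_fraction Passed to
#'   [compute_hrv()].
#' @param alpha,conf Passed to the reliability/validity reports.
#' @return A list of class `hrv_analysis`: `sessions` (session table with
#'   metric columns), `reliability` and `validity` (named lists of reports
#'   per metric), and `exclusions` (tibble of excluded recordings with
#'   reasons).
#' @export
analyze_cohort <- function(cohort,
                           metrics = c("mrr_ms", "rmssd_ms", "hf_ms2",
                                       "hf_nu", "sd1_ms", "pns_index"),
                           window_s = 60,
                           cfg = detrend_config(), bands = spectral_bands(),
                           normals = pns_normals(), threshold_scale = 5.2,
                           gate_fraction = 0.05, alpha = 0.05, conf = 0.95) {
  if (is.character(cohort) && length(cohort) == 1L) {
    cohort <- read_cohort(cohort)
  }
  sessions <- if (inherits(cohort, "hrv_cohort")) {
    cohort$sessions
  } else {
    validate_session_table(cohort)
  }

  if ("rr" %in% names(sessions)) {
    res <- purrr::map(sessions$rr, function(s) {
      tryCatch({
        if (is.null(s)) {
          abort_vmhrv("recording unreadable or missing", "vmhrv_error_io")
        }
        seg <- segment_last(as_rr_series(s), window_s)
        compute_hrv(seg, cfg = cfg, bands = bands, normals = normals,
                    threshold_scale = threshold_scale,
                    gate_fraction = gate_fraction)
      }, vmhrv_error = function(e) {
        tibble::tibble(
          mrr_ms = NA_real_, mean_hr_bpm = NA_real_, rmssd_ms = NA_real_,
          hf_ms2 = NA_real_, hf_nu = NA_real_, sd1_ms = NA_real_,
          pns_index = NA_real_, fraction_corrected = NA_real_,
          quality_pass = FALSE, fail_reason = conditionMessage(e)
        )
      })
    }) |>
      dplyr::bind_rows()
    sessions <- dplyr::bind_cols(
      dplyr::select(sessions, -dplyr::any_of(c("rr", "quality_pass",
                                               names(res)))),
      res
    )
  }

  exclusions <- sessions |>
    dplyr::filter(!.data$quality_pass | is.na(.data$quality_pass)) |>
    dplyr::select(dplyr::all_of(session_key_cols),
                  dplyr::any_of(c("fail_reason", "fraction_corrected")))

  metrics <- intersect(metrics, names(sessions))
  rel <- purrr::map(metrics, function(m) {
    reliability_report(sessions, m, conf = conf, alpha = alpha)
  })
  names(rel) <- metrics
  val <- purrr::map(metrics, function(m) {
    validity_report(sessions, m, reliability = rel[[m]], alpha = alpha,
                    conf = conf)
  })
  names(val) <- metrics

  structure(
    list(sessions = sessions, reliability = rel, validity = val,
         exclusions = exclusions),
    class = "hrv_analysis"
  )
}

#' @export
print.hrv_analysis <- function(x, ...) {
  cat(sprintf(
    "<hrv_analysis: %d sessions, %d excluded, metrics: %s>\n",
    nrow(x$sessions), nrow(x$exclusions),
    paste(names(x$reliability), collapse = ", ")
  ))
  invisible(x)
}

#' Write / read a cohort directory
#'
#' Serializes a generated cohort as text artifacts: one R-R file per
#' session under `rr/`, the session table as `sessions.csv`, and the
#' latent ground truth as `ground_truth.json`. `read_cohort()` restores the
#' cohort from such a directory.
#'
#' @param cohort An `hrv_cohort` with signals.
#' @param dir Target directory.
#' @param force Overwrite a non-empty directory?
#' @return `dir` (invisibly) for `write_cohort()`; an `hrv_cohort` for
#'   `read_cohort()`.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  if (!"rr" %in% names(cohort$sessions)) {
    abort_argument("Cohort has no signal recordings to write.")
  }
  if (dir.exists(dir) && length(dir(dir)) && !force) {
    abort_vmhrv(sprintf("Directory '%s' is not empty (use force = TRUE).",
                        dir), "vmhrv_error_refusal")
  }
  dir.create(file.path(dir, "rr"), recursive = TRUE, showWarnings = FALSE)
  sess <- cohort$sessions
  fname <- sprintf("%s_p%d_%s_%s_%s.txt", sess$subject_id, sess$phase,
                   sess$game, sess$level, sess$timepoint)
  for (i in seq_len(nrow(sess))) {
    write_rr_text(sess$rr[[i]], file.path(dir, "rr", fname[i]))
  }
  out <- dplyr::mutate(dplyr::select(sess, -"rr"), rr_file = fname)
  readr::write_csv(out, file.path(dir, "sessions.csv"), progress = FALSE)
  truth <- cohort$truth
  truth$artifacts <- purrr::map(truth$artifacts, as.list)
  jsonlite::write_json(
    list(config = unclass(cohort$config), truth = truth),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  sess_path <- file.path(dir, "sessions.csv")
  if (!file.exists(sess_path)) {
    abort_argument(sprintf("'%s' is not a cohort directory (no sessions.csv).",
                           dir))
  }
  sess <- readr::read_csv(sess_path, show_col_types = FALSE, progress = FALSE)
  sess$rr <- purrr::map(sess$rr_file, function(f) {
    tryCatch(read_rr_text(file.path(dir, "rr", f)),
             vmhrv_error = function(e) NULL)
  })
  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  structure(list(sessions = tibble::as_tibble(sess),
                 truth = truth$truth, config = truth$config),
            class = "hrv_cohort")
}

#' Markdown summary of an analysis
#'
#' Renders a compact human-readable report: per-metric mean and range of
#' ICC, SEM% and SDD%, eligibility and validity verdicts, and the exclusion
#' log.
#'
#' @param analysis An `hrv_analysis` from [analyze_cohort()].
#' @param path Optional file to write the markdown to.
#' @return The markdown lines, invisibly when `path` is given.
#' @export
report_markdown <- function(analysis, path = NULL) {
  stopifnot(inherits(analysis, "hrv_analysis"))
  lines <- c("# vm-HRV reliability & validity report", "")
  any_est <- FALSE
  for (m in names(analysis$reliability)) {
    g <- glance(analysis$reliability[[m]])
    lines <- c(lines, sprintf("## %s", m))
    if (g$n_conditions == 0L) {
      lines <- c(lines, "no estimable conditions", "")
      next
    }
    any_est <- TRUE
    lines <- c(lines, sprintf(
      "- ICC(3,1) mean %.3f (range %.3f to %.3f) over %d conditions",
      g$icc_mean, g$icc_min, g$icc_max, g$n_conditions
    ))
    if (is.finite(g$sem_pct_mean)) {
      lines <- c(lines, sprintf(
        "- SEM%% mean %.1f (range %.1f to %.1f); SDD%% mean %.1f (range %.1f to %.1f)",
        g$sem_pct_mean, g$sem_pct_min, g$sem_pct_max,
        g$sdd_pct_mean, g$sdd_pct_min, g$sdd_pct_max
      ))
    }
    v <- analysis$validity[[m]]
    gv <- glance(v)
    verdict <- if (gv$n_eligible > 0L && gv$n_pairwise_significant > 0L) {
      "eligible and demand-level sensitive: valid at group level"
    } else if (gv$n_eligible > 0L) {
      "eligible but no significant demand-level separation"
    } else {
      "not eligible (reliability gate)"
    }
    lines <- c(lines, sprintf("- validity: %s (%d/%d conditions eligible)",
                              verdict, gv$n_eligible, gv$n_conditions), "")
  }
  if (!any_est && !length(names(analysis$reliability))) {
    lines <- c(lines, "no estimable conditions", "")
  }
  nex <- nrow(analysis$exclusions)
  lines <- c(lines, "## Exclusions",
             sprintf("- %d recording(s) excluded", nex))
  if (nex > 0 && "fail_reason" %in% names(analysis$exclusions)) {
    reasons <- table(analysis$exclusions$fail_reason, useNA = "ifany")
    lines <- c(lines, sprintf("  - %s: %d", names(reasons), reasons))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
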