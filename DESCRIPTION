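Package: vmhrv
Title: Reliability and Validity Analysis of Vagally Mediated Heart Rate
    Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether vagally mediated heart rate
    variability (vm-HRV) parameters are reliable and valid markers of
    internal training load. Reads R-R inter-beat-interval recordings,
    detects and corrects abnormal beats, removes slow trends with the
    smoothness-priors method, and computes the vm-HRV parameter set (mean
    R-R interval, RMSSD, high-frequency power and its normalized form,
    Poincare SD1, and a parasympathetic tone index). Provides the
    three-level test-retest reliability analysis (repeated-measures or
    rank-based ANOVA-type tests for systematic error, ICC(3,1) with exact
    confidence intervals, standard error of measurement and smallest
    detectable difference), a reliability-gated validity analysis with
    Bonferroni-corrected post-hoc comparisons and effect sizes, precision
    based sample-size planning for ICC studies, exercise-intensity
    prescription helpers (Karvonen target, ramp test, NASA-TLX scoring),
    and a ground-truth synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
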