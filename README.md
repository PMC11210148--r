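# vmhrv

Is vagally mediated heart rate variability (vm-HRV) a usable marker of
internal training load? `vmhrv` implements the full decision pipeline a
sports-science or geriatrics group needs to answer that question for a
test-retest study design: R-R interval ingestion and windowing, automatic
beat correction with a strict data-quality gate, smoothness-priors
detrending, the vm-HRV parameter set (mRR, RMSSD, HF, HFnu, SD1,
PNS index), a three-level test-retest reliability analysis, a
reliability-gated validity analysis across standardized task-demand
levels, ICC-precision sample-size planning, exercise-intensity
prescription helpers, and a ground-truth synthetic cohort generator that
makes every stage testable without any recorded data.

## The statistics at the core

For each metric and each *phase × game × demand-level* condition with
paired test/retest measurements:

* **Systematic error** — two-way within-subject ANOVA
  (timepoint × level) with Mauchly's test and Greenhouse–Geisser
  correction, or a rank-based ANOVA-type statistic (ATS) when
  Shapiro–Wilk screening rejects normality in any design cell.
* **Relative reliability** — consistency ICC(3,1),
  `(MS_R − MS_E) / (MS_R + (k−1) MS_E)`, with its exact F-bound 95% CI and
  interpretation bands (poor < 0.5 ≤ fair < 0.75 ≤ good < 0.9 ≤ excellent).
* **Absolute reliability** — `SEM = SD_pooled · sqrt(1 − ICC)`,
  `SDD = 1.96 · sqrt(2) · SEM`, each also as a percentage of the combined
  mean of both occasions.
* **Validity** — only metrics with ICC ≥ 0.5 at *all three* levels are
  eligible; given a significant level main effect and no interaction, the
  three level pairs are compared with Bonferroni-corrected paired t-tests
  (effect size `r = |t|/sqrt(n)`) or Wilcoxon signed-rank tests
  (`r = |Z|/sqrt(N)`).
* **Planning** — `sample_size_icc()` returns the minimum n for a desired
  ICC confidence-interval width with a stated assurance probability
  (Bonett closed form corrected against the exact F-interval).

## Worked example

Score a single resting recording (a synthetic 5-min fixture ships with the
package):

```r
library(vmhrv)

rest <- read_rr_text(system.file("extdata", "synthetic_rest_300s.txt",
                                 package = "vmhrv"))
rest
#> <rr_series: 327 beats, 300.6 s, mean RR 919.2 ms>

compute_hrv(rest)[1:7]
#>   mrr_ms mean_hr_bpm rmssd_ms  hf_ms2 hf_nu sd1_ms pns_index
#>  919.192      65.275   35.119 601.793 0.668 24.833     0.259
```

A mean R-R of 919 ms (65 bpm), RMSSD 35 ms and HF power ~600 ms² with
two-thirds of the non-VLF power in the respiratory band describe a
resting, parasympathetically dominant state; the PNS index of +0.26 sits
just above the normative resting mean.

Run the whole study pipeline on a simulated test-retest cohort (20
subjects, two games, three demand levels, target ICC 0.85):

```r
coh <- generate_cohort(cohort_config(n_subjects = 20,
                                     games = c("Simple", "Tetris"),
                                     seed = 7))
an  <- analyze_cohort(coh, metrics = "mrr_ms")

an$reliability$mrr_ms[, c("game", "level", "n", "icc", "icc_band",
                          "sem_pct", "sdd_pct")]
#>     game       level  n   icc  icc_band sem_pct sdd_pct
#> 1 Simple        easy 20 0.867      good   4.165  11.545
#> 2 Simple challenging 20 0.879      good   4.174  11.569
#> 3 Simple   excessive 19 0.892      good   4.416  12.240
#> 4 Tetris        easy 20 0.878      good   4.302  11.925
#> 5 Tetris challenging 20 0.855      good   5.177  14.351
#> 6 Tetris   excessive 20 0.930 excellent   3.685  10.214

tidy(an$validity$mrr_ms)[, c("game", "comparison", "p_adj", "r", "r_band")]
#>     game               comparison   p_adj    r r_band
#> 1 Simple      easy vs challenging 7.5e-06 1.55  large
#> 2 Simple        easy vs excessive 1.2e-08 2.42  large
#> 3 Simple challenging vs excessive 1.1e-07 2.09  large
#> 4 Tetris      easy vs challenging 4.9e-07 1.79  large
#> 5 Tetris        easy vs excessive 3.6e-11 3.21  large
#> 6 Tetris challenging vs excessive 3.9e-08 2.11  large
```

Reading the output: every condition shows good-to-excellent test-retest
reliability (ICC 0.86–0.93 against the generator's target of 0.85; one
`n = 19` marks a recording excluded by the 5% beat-correction gate), SEM%
around 4–5% of the condition mean, and — since all level ICCs clear the
0.5 eligibility gate — all three demand-level contrasts separate with
large effect sizes, i.e. mRR is both reliable and demand-sensitive in this
cohort. `glance()` summarizes a report, `autoplot()` draws the ICC forest,
and `report_markdown(an)` renders the whole analysis as text.

Planning a new reliability study:

```r
sample_size_icc(rho0 = 0.75, width = 0.3, conf = 0.95, assurance = 0.5)
#> [1] 38
```

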