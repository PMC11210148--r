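---
title: "Methods: reliability and validity of vagally mediated HRV as a training-load marker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability and validity of vagally mediated HRV as a training-load marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmhrv)
```

## The problem

Internal training load (ITL) — the psychophysiological response an
individual mounts to an imposed task — is what adaptive training should be
dosed against, but it is not directly observable. Vagally mediated heart
rate variability (vm-HRV) is an attractive candidate marker: the
parasympathetic contribution to beat-to-beat variability reacts within
seconds to changes in cognitive and physical demand. Before vm-HRV can be
used to steer training (for example exergame difficulty for older adults),
two questions must be answered for each candidate parameter:

1. **Reliability** — does the parameter reproduce itself when the same
   person repeats the same standardized task a few days later?
2. **Validity** — once measurement error is known, does the parameter
   actually move when task demand moves?

`vmhrv` implements this entire decision pipeline — signal ingestion, beat
correction, detrending, metric computation, the three-level reliability
analysis, the reliability-gated validity analysis, and sample-size planning
— together with a ground-truth cohort generator so every stage can be
tested end-to-end without any recorded data.

## Signal model and preprocessing

The atomic object is the R-R interval series: inter-beat intervals in
milliseconds at 1 ms resolution, with each beat timestamped by its
terminating R peak. Windows follow the tachogram convention (a beat belongs
to `(t0, t1]` if it *ends* there), so adjacent windows partition a
recording exactly. Resting segments are scored over a full 5-min window;
on-task trials over their trailing 60 s, where `segment_last()` prefers
overshooting by less than one beat to undershooting — never analyzing less
data than prescribed.

**Beat correction.** Abnormal beats are flagged by comparing each beat's
deviation from a running 11-beat median against a time-varying threshold of
`threshold_scale` (default 5.2) local quartile deviations, with the
successive-difference (dRR) series driving the subtype patterns: a single
interval near twice the local median is a missed beat (split on
correction), a short pair summing to the local median is a spurious extra
detection (merged), and short–long alternation marks ectopic or misaligned
timing (replaced by local interpolation, rescaled so the affected span
keeps its duration). Corrections redistribute time, never delete it; total
duration is preserved within 2%. A segment enters the analysis only if
*strictly fewer than 5%* of its beats needed correction; failed segments
become missing records, never zeros — zeros would silently corrupt every
downstream ICC.

**Detrending.** Slow non-stationarities are removed with the
smoothness-priors method: the tachogram is cubic-spline resampled to a
4 Hz grid, the trend is the ridge solution
$z_{trend} = (I + \lambda^2 D_2^T D_2)^{-1} z$ with second-difference
penalty matrix $D_2$ (natural boundary, no padding), and the residual is
mapped back to beat times. At the defaults ($\lambda = 500$, 4 Hz) the
empirical half-power cutoff is ≈ 0.03 Hz: a 0.01 Hz drift is attenuated by
more than 90% while a 0.25 Hz respiratory oscillation passes essentially
untouched (both are asserted as tests). Because the detrended series is
zero-mean by construction, the mean R-R interval is always computed on the
*undetrended* corrected series; RMSSD, SD1 and all spectra are computed on
the detrended one. This split mirrors standard HRV-software behaviour.

## The vm-HRV parameter set

For each analyzable segment the package computes mean R-R (mRR, ms), mean
HR (bpm), RMSSD (ms), absolute high-frequency power HF (0.15–0.4 Hz, ms²),
normalized HF power $HF_{nu} = HF / (TP - VLF)$, Poincaré SD1 (ms), and a
parasympathetic tone index (PNS).

Numerical conventions worth stating explicitly:

* **SD1** is computed in its RMS form $\sqrt{\overline{\Delta RR^2}/2}$,
  so the identity $SD1 = RMSSD/\sqrt{2}$ holds exactly for every input and
  is asserted globally in the tests.
* **Spectra** use Welch's method: Hann window, 50% overlap, segment length
  `min(150 s, duration)`. On 60-s on-task windows this degrades to a single
  tapered periodogram; the coarse resolution (Δf ≈ 0.017 Hz) is acceptable
  because only band *integrals* (rectangle rule) are consumed. A pure
  0.25 Hz sinusoid of amplitude $A$ recovers $A^2/2$ of HF power within
  10%, and white noise satisfies Parseval within 15% — both closed-form
  oracles in the tests. No R package in the supported stack provides a
  Welch estimator, so it is implemented directly on `stats::fft()`.
* **PNS index** is the equal-weight mean of three standardized deviations,
  $z(mRR)$, $z(RMSSD)$ and $z(SD1_{nu})$ with
  $SD1_{nu} = SD1/(SD1+SD2)$ and $SD2 = \sqrt{2\,SDNN^2 - SD1^2}$ computed
  from the same segment. Normative constants are configuration
  (`pns_normals()`), defaulting to round published resting values
  (mRR 926 ± 90 ms, RMSSD 42 ± 25 ms, SD1nu 0.30 ± 0.10): the *structure*
  of the index is what the reliability analysis needs; its absolute
  calibration is not load-bearing.
* An undefined metric (e.g. $HF_{nu}$ when $TP \le VLF$) is recorded as
  missing, never coerced to 0.

## Exercise-intensity prescription

Phase-2 style protocols keep physical intensity constant while game demand
varies. The helpers implement the standard tools: age-predicted maximal HR
($208 - 0.7 \cdot age$), the Karvonen target
($HR_{target} = (HR_{max} - HR_{rest}) \cdot f + HR_{rest}$, default
$f = 0.40$, the lower bound of the moderate 40–59% HRR band), a ramp test
(start 80 steps/min, +5 every 20 s, first stage whose 20-s-averaged HR
meets the target; the result is always on the cadence grid), an inclusive
±5 bpm resting-HR stability rule, the raw NASA-TLX (unweighted sum of six
0–20 subscales), and rest-to-task reactivity (absolute metric deltas).
Ages are accepted as reals — the formula is continuous.

## Three-level reliability analysis

For each metric × phase × game × demand level:

1. **Systematic error.** A balanced two-way within-subject ANOVA
   (timepoint × level) per game, each factor tested against its own
   subject-interaction stratum. Sphericity of the 3-level factor and of the
   interaction is checked with Mauchly's test on the respective contrast
   covariances; when violated (p ≤ 0.05), Greenhouse–Geisser ε rescales
   that term's degrees of freedom. The 2-level timepoint factor needs no
   correction (ε ≡ 1). When any design cell fails Shapiro–Wilk screening
   (p ≤ 0.05, or a constant cell where the test is undefined), the
   parametric ANOVA is replaced *wholesale* by the rank-based ANOVA-type
   statistic (ATS): joint mid-ranks, projection quadratic forms, Box-type
   numerator df from the empirical covariance of subject rank vectors.
   One-df hypotheses are referred to $F(\hat f, n-1)$ (a squared rank
   paired-t), multi-level hypotheses to $F(\hat f, \infty)$; this hybrid
   was chosen because it holds the empirical type-I rate of *all* terms
   within [0.035, 0.065] at n = 20, which the pure $F(\hat f, \infty)$
   reference does not for the 2-level factor. (A Wald-type statistic is a
   known alternative in this family; the ATS was chosen for its stability
   at the study's sample sizes.)
2. **Relative reliability.** ICC(3,1): two-way mixed, single measures,
   *consistency* — $(MS_R - MS_E)/(MS_R + (k-1) MS_E)$ — with the exact
   F-bound 95% CI. The estimate is verified against a brute-force
   mean-squares oracle to 1e-10 in the tests. Bands: poor < 0.50 ≤ fair
   < 0.75 ≤ good < 0.90 ≤ excellent (left-closed).
3. **Absolute reliability.** $SEM = SD_{pooled}\sqrt{1 - ICC}$ with the
   pooled SD across both occasions (the standard Weir formulation — a
   literal standard-error-of-the-mean would not reproduce the fixed
   $SDD = 1.96\sqrt{2}\,SEM$ ratio), and SEM%, SDD% normalized by the
   combined mean of both occasions.

Missing or incomplete subjects are dropped pairwise-complete per condition
for the ICC/SEM block and complete-case per game for the ANOVA, so
per-condition n may differ by game. No multiplicity correction is applied
across the metric × game × level grid; Bonferroni applies only within
post-hoc pairwise tests. The joint 2×3 design (both levels and timepoints
in one ANOVA per game) is used throughout.

## Reliability-gated validity

A metric is eligible for validity testing only with at least fair
reliability (ICC(3,1) ≥ 0.5, inclusive) at *all three* demand levels.
Given eligibility, a significant level main effect (p ≤ 0.05, two-sided)
and no significant timepoint × level interaction, the three level pairs
are compared post hoc — paired t-tests or Wilcoxon signed-rank tests
following the same branch routing — with Bonferroni correction
($p_{adj} = \min(1, 3p)$) on subject-wise means over the two occasions.
Refusals carry their reason; post-hocs are never silently computed.

Effect sizes use a dual convention, both labelled in output: the
parametric branch reports $r = |t|/\sqrt{n_{pairs}}$ (unbounded above 1 —
the scale on which such analyses conventionally report paired
comparisons), the nonparametric branch $r = |Z|/\sqrt{N}$ with N the
observation count. The signed-rank test uses the exact null for ≤ 25
non-zero pairs without ties and the tie/continuity-corrected normal
approximation otherwise; zero differences are dropped and counted. Bands:
negligible < 0.1 ≤ small < 0.3 ≤ medium < 0.5 ≤ large (the conventional
banding leaves r = 0.5 itself unassigned; it is classified large here).

## Sample-size planning for ICC precision

`sample_size_icc()` plans the number of subjects so that the 95% CI of an
anticipated ICC has width ≤ w with a stated assurance probability. It
starts from Bonett's closed form
$n = 8 z^2 (1-\rho)^2 (1+(k-1)\rho)^2 / (k(k-1)w^2) + 1$ and then corrects
it against the exact F-bound interval, exploiting that the ANOVA F ratio is
$\tau F_{n-1,(n-1)(k-1)}$ with $\tau = (1+(k-1)\rho)/(1-\rho)$: with 50%
assurance the criterion is the *expected* CI width (integrated over the
estimator's sampling distribution — the closed form's own target, which
the approximation underestimates at k = 2, and slightly conservative
relative to the median because the width distribution is right-skewed);
with higher assurance it is the corresponding exact width quantile. At
(ρ₀ = 0.75, w = 0.3, 95%, 50%, k = 2) the closed form alone gives 34,
the expected-width criterion 38 (E[width] = 0.302 at n = 37, 0.297 at
n = 38).

## The synthetic cohort generator

`generate_cohort()` defines the study conditions every test runs under.
Each beat is
$RR_i = \mu + A_{hf}\sin(2\pi f_{resp} t_i) + A_{lf}\sin(2\pi\,0.1\,t_i + \phi) + A_{tr}\sin(2\pi\,0.01\,t_i + \psi) + \varepsilon_i$,
with $\mu$ the subject baseline plus the demand-level shift plus occasion
noise. Defaults describe an older-adult cohort: 43 subjects, five games,
three levels, baseline RR 850 ± 80 ms between subjects, level shifts
(0, −50, −100) ms (RR shortens as demand rises), respiratory amplitude
(40, 30, 20) ms by level (vagal withdrawal with demand) at 0.25 Hz, LF
25 ms, slow trend 30 ms, white beat noise 10 ms, 90-s trials and 300-s
rests. The target test-retest ICC defaults to 0.85 and is imposed
*analytically*: occasion noise on the latent condition mean has
$\sigma_o = \sigma_b\sqrt{1/\rho - 1}$, so the induced intraclass
correlation of latent condition-level mRR equals ρ exactly. This is why
parameter-recovery tests can demand tight envelopes: in latent mode
(`signals = FALSE`) cohorts at ρ ∈ {0.5, 0.75, 0.9} recover the target to
±0.05 in mean with ~95% CI coverage over 100 replicates.

The deterministic-sinusoid HF component (rather than an integral pulse
frequency modulation model) is a deliberate choice: it makes band-power
oracles closed-form ($A^2/2$), at the price of a less physiological
spectrum. Per-beat noise and the slow trend add a small, known attenuation
of the *measured* ICC relative to the latent target in full-signal mode
(the trend's random phase moves 60-s window means between occasions);
end-to-end tests therefore assert recovery at wider tolerances than latent
mode. Artifacts are injected with ground truth (merge = missed,
split = extra, ±20–40% timing shift = ectopic), which is how the ≥ 90%
detection-sensitivity and gate-interaction tests get their truth.

What passing tests do **not** show about real data: real respiratory
frequency drifts and is amplitude-modulated; ectopy is not uniformly
random; occasion effects include circadian and behavioural structure; and
the generator models none of the adaptive-difficulty coupling a live
exergame introduces. The generator validates the *statistical machinery*,
not the physiology.

## Problem sizes and runtime choices

Test problem sizes were chosen to keep the full suite in the low minutes
on one core while leaving Monte-Carlo margins comfortable: type-I
calibration uses 2000 null replicates of the 2×3 design at n = 20 (band
0.05 ± 0.015); ICC recovery uses 100 cohorts per target ICC at n = 43;
end-to-end checks run the full default 43 × 5-game cohort (1290
recordings) once for the effect direction and once as an identity cohort
(retest ≡ test, the reliability ceiling: ICC = 1, SEM% = 0 everywhere).

## Known limitations

* The quality gate counts corrected beats in whatever segment it is given;
  the pipeline applies it per analyzed window, not per whole recording —
  for 90-s trials scored on their last 60 s the two differ.
* The beat-correction scheme reproduces the *behaviour* of validated
  automatic correction (quartile-deviation thresholds, subtype patterns)
  but is not a reimplementation of any proprietary tool; its thresholds
  floor the quartile deviation at 0.01 ms so noise-free synthetic series
  divide cleanly.
* Consistency ICC(3,1) ignores additive session shifts by construction;
  systematic error must be read from the ANOVA column, not the ICC.
* The percentage normalizations (SEM%, SDD%) are undefined at zero grand
  mean and unstable near it — relevant for signed indices like the PNS
  score.
* Spectral estimates on 60-s segments have Δf ≈ 0.017 Hz; VLF power in
  such segments is dominated by leakage and is reported only as a
  component of the $HF_{nu}$ denominator.
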