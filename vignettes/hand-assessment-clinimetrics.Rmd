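---
title: "Clinimetric evaluation of robot-assisted hand assessments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinimetric evaluation of robot-assisted hand assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `handassess`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the numerical and
design choices taken where more than one reasonable option existed.

## The assessment battery and its conventions

All angles refer to the index-finger metacarpophalangeal (MCP) joint, with
neutral at 0 degrees, flexion positive and extension negative. The simulated
device workspace is [-30, +60] degrees from neutral; simulated positions are
saturated there and clipping events counted (`clip_workspace()`). Signals
are nominally sampled at 1 kHz; velocity and force channels are conditioned
with a first-order Butterworth low-pass at 20 Hz before feature extraction.

One assessment comprises: 21 position-matching trials (the integers 10..30
degrees flexion, each presented once in seeded random order), 20 reaching
trials (10 per direction; flexion runs -10 to +30 degrees, extension 30 to
-10, with a 4 s response window), 3 active plus 3 passive range-of-motion
repetitions, 3 force trials per direction, and 6 tracking trials (3 slow,
3 fast). The tracking target is a sum of three sines around a 15-degree
centre (slow: 0.03/0.07/0.13 Hz; fast: 0.10/0.20/0.40 Hz). The protocol
phrase assigning the three components "the same amplitude" of 15 degrees is
ambiguous between 15 degrees per component (peak excursion up to 45
degrees, beyond the workspace) and a 15-degree total; the default splits 15
degrees equally across components (5 degrees each, workspace-feasible),
with `amplitude_mode = "strict"` available for the literal reading.

### The low-pass filter

`lowpass()` applies the exact analog first-order Butterworth transfer
function `H(f) = 1/(1 + i f/fc)` in the frequency domain (with reflection
padding against wrap-around), retaining the causal phase by default and
squaring the magnitude with zero phase when `zero_phase = TRUE`. The reason
for a frequency-domain implementation is accuracy of the magnitude
response: at a 1 kHz sampling rate a bilinear-transform digital design
attenuates a 200 Hz component to 0.086 of its amplitude and an
impulse-invariant design to 0.106, while the analog response is 0.0995;
for offline feature extraction the analog response is the better-defined
contract, and it makes the filter's behaviour exactly the analytic
`1/sqrt(1 + (f/fc)^2)` at every frequency below Nyquist. The trade-off is
the mild assumption of negligible signal energy at the spectrum edges,
which the padding addresses.

## Test-retest reliability

For each metric and body side, per-subject session means form an
`n x 2` panel. Reliability statistics:

* **ICC(A,k)** — absolute-agreement, average-measures intraclass
  correlation from the two-way ANOVA (subjects x sessions),
  `(MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)`. The confidence interval is
  the F-based interval of the single-measures form stepped up with
  Spearman-Brown; it reproduces pingouin's `ICC(A,k)` output to machine
  precision. The interval is approximate and can fail to bracket the point
  estimate for degenerate panels with near-zero ICC. Acceptability
  threshold: strictly above 0.7.
* **SEM / SRD** — the SEM is the square root of the error variance of the
  session-level outcome (the ANOVA `MS_E`). When trial-level values are
  available, a nested decomposition splits this into a trial-replicate
  component (pooled within-cell variance) and a session-level excess, both
  reported; `basis = "trial"` re-expresses the SEM for a single-trial
  measurement. The published SRD values this package's preset is calibrated
  against are not exactly reconstructible from either reading alone, so the
  error-term-of-the-aggregate form was chosen as the default and the
  alternative kept one flag away. `SRD = 1.96 sqrt(2) SEM`; SRD% divides by
  the observed range of pooled trial-level values across all subjects and
  sessions (threshold: strictly below 30%).
* **Systematic shift** — mean retest-minus-test difference as a percentage
  of that same pooled range, sign-oriented through each metric's direction
  of better performance so that positive always means worse on retest
  (bound: within +-6.35, inclusive).
* **Bland-Altman** limits of agreement and the test-retest Spearman
  correlation complete the report.

## Validity

Group comparisons pool both hands of control subjects (62 control hands at
the default cohort size) against the affected and less-affected sides of
stroke subjects: Kruskal-Wallis omnibus with the three pairwise follow-ups
Bonferroni-corrected (m = 3, capped at 1), plus ROC AUCs computed as
midrank Mann-Whitney `U/(n1 n2)`, oriented so that AUC > 0.5 always means
patients perform worse. Body sides are additionally compared with a paired
t-test.

**Confound removal.** On control trial-level data, each task gets a linear
mixed model `value ~ age + gender + hand + task_effect + trial_num +
(1 | subject)` (REML, Satterthwaite t-tests). The task-specific effect is
the movement direction, ROM mode or trajectory speed — or the presented
angle for position matching, whose error grows with angle magnitude. Model
quality is summarised by `C1 = 100 mean(|resid|)/range` and
`C2 = 100 sd(|resid|)/range` (good: C1 <= 10 and C2 <= 20; moderate:
C1 <= 15 and C2 <= 25); these formulas are a declared interpretation of
criteria whose exact definitions live in prior work, isolated in one
function so they can be swapped. Fixed-effect predictions relative to
reference covariate values are subtracted from metric values before
z-scoring. By default the removal applies to motor-category metrics only
(the category the confounds demonstrably affect), extendable to all via
`adjust = "all"`.

**Impairment classification.** Adjusted patient values are standardised
against the adjusted control distribution and oriented so larger z is
worse. "Worse than the 95th percentile of controls" is implemented by
default as the one-sided 95% normative limit
`qt(0.95, n-1) sqrt(1 + 1/n)` on the z scale: with a finite control sample
the plug-in empirical percentile flags clearly more than 5% of genuinely
unimpaired subjects (about 6.4% at n = 62), whereas the prediction-bound
form is exactly nominal under normality. The plug-in normal deviate and the
empirical percentile remain available as options; the inequality is strict
in all cases. Patients use session-1 means (the session every subject has).

**Concurrent validity and independence.** Affected-side metric values are
Spearman-correlated with FMA, side-matched BBT and kUDT; strengths are
labelled negligible (< 0.1), weak (0.1-0.39), moderate (0.4-0.69) and
strong (>= 0.7) on the absolute value. Classification agreement compares
robot impairment calls with FMA < 60 (motor and sensorimotor metrics) and
kUDT < 2 (sensory and sensorimotor). The independence analysis computes
partial Spearman correlations between one representative metric per domain
(defaults: AE, VelExt, AROM, ForceFlex, RMSESlow); because no covariate set
is canonical for this analysis, each pair is controlled for all remaining
selected metrics by default, and the choice is a parameter recorded in the
output.

## The synthetic cohort generator

The generator's purpose is to emulate the statistical structure the
analysis assumes, not finger biomechanics. Two latent severities on [0, 1]
drive everything: `s_motor` loads on the reaching, ROM and force metrics,
`s_proprio` on position matching, and the tracking task loads on both
(0.65/0.35 slow, 0.45/0.55 fast), operationalising the observation that
tracking error travels with proprioceptive error rather than with the
motor metrics. Severities are moderately correlated (Gaussian copula,
rho = 0.4) and the cohort honours a design constraint of at most 40% of
stroke subjects with intact proprioception (kUDT = 2).

Per metric, a subject's expected level is a multiplicative severity map
`m(s) = m_control r^(2s)`, with `r` solved per metric so that a uniform
severity mix averages exactly to the configured stroke target mean — the
calibrated preset uses the published affected-side test-session means and
SDs (e.g. AE 14.63 +- 6.43 deg, VelExt 149.06 +- 146.27 deg/s, AROM
43.89 +- 36.20 deg, ForceFlex 11.64 +- 11.55 N, RMSESlow 21.09 +- 8.68
deg). The exponential map keeps levels positive without the mean bias a
clipped linear map would introduce. Around the expected level, subjects
scatter with a gamma distribution whose spread interpolates from the
control SD (so the null preset reproduces the control distribution
exactly) and is bounded by a coefficient of variation of 1.2, so severely
impaired subjects scatter in proportion to their small expected levels.
Physical caps (90 degrees ROM, the gauge range, plausible force and
velocity maxima) trim impossible tails. Control-hand distributions are a
synthetic plausibility calibration — no published control table is
reproduced — chosen so the implied control-vs-affected separations match
the published AUC levels, including the deliberately borderline passive
ROM (its published AUC sits at 0.69, just below the 0.7 rule, and the
preset preserves that borderline character rather than forcing it above
threshold).

Within-subject structure: each session multiplies the level by a lognormal
session factor and adds the configured relative retest shift (default 0);
trials multiply by lognormal factors with task-specific coefficients of
variation (reaching 0.25, active ROM 0.12, passive ROM 0.05, force 0.15,
tracking 0.18 — chosen once as realistic repeatability levels). The
reaching aggregate (mean of the 3 largest of 10 peaks) is kept unbiased by
dividing the programmed level by the order-statistic constant
E[top-3 mean] = 1.28048 of the trial-noise distribution. The session-level
error coefficient is derived per metric from the published smallest real
differences (SEM = SRD/(1.96 sqrt 2) relative to the stroke mean), minus
the share the trial aggregate already contributes. Position matching is
generated mechanistically even in the fast mode: reported angle = presented
angle + a half-normal error whose scale grows 25% per 10 degrees of
presented angle, reproducing the angle-magnitude effect.

Confounds enter additively with the published signs: age reduces force
(-0.10 N/yr flexion), males produce higher forces and velocities, and the
tested hand shifts the motor metrics slightly; all are centred so the
calibration targets are preserved. Demographics follow the study design
(30 stroke subjects, 64.5 +- 14.0 years, 19 male, two sessions; 31
controls, 66.9 +- 7.9 years, right-handed, one session). Clinical scores
are monotone noisy maps from the severities into their ranges (FMA 0-66,
kUDT 0-2 discretised, BBT per side, MoCA, MAS).

**Trace mode** synthesises raw signals from the same per-trial scalars:
bell-shaped velocity pulses whose time-to-peak lengthens from 122 ms
(intact) to about 198 ms (severe) with position integrated and saturated at
the workspace; smooth ROM excursions (75% of the excursion in flexion);
sigmoid force plateaus; and tracking responses
`centre + gain (target(t - lag) - centre) + wander`, with gain falling and
lag growing with severity and the low-frequency wander iteratively rescaled
after workspace clipping so the realised trial RMSE matches the programmed
value where the workspace allows it. Trace mode exists so the filtering and
extraction code paths are genuinely exercised; the fast metric mode is used
for Monte-Carlo statistics.

What the generator does **not** emulate: real distributions' skew and
bimodality beyond the gamma family, neglect or visual deficits, fatigue or
motivation drift within a session, floor effects of subjects who cannot
move at all (who in real data can paradoxically score better on error
metrics by staying still), or lesion-side asymmetries. Passing tests on
synthetic cohorts therefore demonstrate that the statistical machinery is
correct and well-calibrated under the assumed structure — not that real
assessments will reach any particular reliability level.

## Numerical choices and degenerate inputs

* Zero-variance panels, constant correlation inputs and singular partial
  correlation pairs are flagged (`defined = FALSE` / NA) rather than
  propagating NaN; all-tied Kruskal-Wallis input returns p = 1.
* Zero-variance paired differences short-circuit the paired t-test (p = 1
  for identical sides, p = 0 for a constant nonzero difference, flagged).
* Spearman p-values use the asymptotic tie-corrected form (`exact = FALSE`).
* Threshold semantics are strict (> 0.7 for ICC and AUC, < 30 for SRD%)
  with the shift bound inclusive (|shift| <= 6.35), matching how the
  decision rules are phrased.
* Missing trials degrade gracefully: aggregates use available trials and
  record `n_trials`; a metric with fewer than 3 reaching trials is marked
  missing; a fully missing task drops out of the reports while all other
  metrics are computed.
* All randomness flows from one master seed through per-subject,
  per-session hashed substreams, so regenerating a subset of the cohort is
  stable and two runs with the same seed are identical end to end.

## Problem sizes

The bundled simulation studies use the cohort sizes of the emulated study
(30 + 31 subjects) for pipeline runs; 500 replicates per level for
variance-component recovery (n = 30, 2 sessions, 6 trials per cell); 200
replicate cohorts for shift recovery, confound recovery and normative
calibration; 5000 null replicates for the Kruskal-Wallis type-I rate; 100
replicate cohorts for the end-to-end qualitative reproduction; and 1000
random panels per statistic for the brute-force oracle comparisons. The
generator self-calibration check uses 600 simulated stroke subjects, where
the Monte-Carlo error of the heavy-tailed force metrics' means is well
inside the 10% tolerance.

## Known limitations

The ICC confidence interval is approximate (and the point estimator itself
carries a small negative finite-sample bias at low ICC with only two
sessions — about -0.04 at ICC 0.5 with 30 subjects when between-session
variance is absent). The C1/C2 quality formulas are an interpretation, as
is the exact SEM basis; both are isolated behind single functions. The
confound model assumes additive, linear covariate effects and a normal
random intercept; the normative limit assumes approximate normality of
adjusted control values. The generator's lognormal-gamma structure is a
modelling convenience, and its control-hand presets are synthetic.
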