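---
title: "Anticipatory smooth eye movements and interception latency: methods"
author: "anticept"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anticipatory smooth eye movements and interception latency: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anticept)
```

## The problem

Before a moving object appears, observers who can predict its direction
drift their eyes slowly in that direction — anticipatory smooth eye
movements (ASEMs). `anticept` implements an analysis chain for experiments
that ask whether this oculomotor anticipation speeds up the *hand*: a
random-dot motion (RDM) cue with signed coherence
$x \in \{-0.64,\dots,0.64\}$ predicts the direction of a target that then
moves horizontally at 8 deg/s, and the participant intercepts it with a
stylus-driven cursor. The pipeline goes from raw 1 kHz eye and 60 Hz
cursor traces to three claims: (i) ASEM velocity follows a sigmoid of
signed coherence whose height depends on whether fixation is released
(gap) or held (control); (ii) interception latency follows a peaked
(Gaussian) curve over coherence; (iii) trial-by-trial, faster anticipation
predicts earlier interception, captured by linear mixed-effects (LME)
models compared with BIC.

## Signal chain

Eye position is low-pass filtered (second-order Butterworth, 15 Hz
passband), differentiated with central differences, and velocity and
acceleration are filtered at 30 Hz. Saccades are flagged where velocity
exceeds 30 deg/s jointly with |acceleration| above 1000 deg/s²; each
flagged interval grows to the surrounding run of above-criterion velocity,
is padded, and the position trace is bridged linearly ("desaccading")
before velocity is recomputed. Cursor position is filtered at 20 Hz;
cursor velocity and acceleration come from central differences of the
filtered position without a second filter, because a 30 Hz velocity
passband would sit exactly at the 60 Hz Nyquist frequency.

Two filtering decisions deserve comment.

* **Zero-phase filtering.** The filters are applied forward and backward
  (`signal::filtfilt` with odd-reflection padding). Every downstream
  quantity is an event time (interception onset, ASEM window), so phase
  shift is unacceptable; the price is that the effective magnitude
  response is the *square* of the second-order design, and the tests
  check attenuation against that squared response.
* **Desaccade padding of ±25 ms.** The 15 Hz position filter smears a
  saccade well beyond the samples that exceed the velocity criterion.
  With a narrow (10 ms) pad the bridged gap still contains smeared
  saccade tails and the recomputed velocity inside the gap can exceed the
  30 deg/s criterion, defeating the purpose of desaccading; 25 ms spans
  the tails at these passbands. The pad is configurable
  (`analysis_config(saccade_pad = )`).

Per-trial scalars follow the field's definitions: ASEM velocity is the
mean horizontal desaccaded velocity in the closed ±50 ms window around
target motion onset; interception onset is the first sample with 2-D
cursor speed above 1.0 deg/s, searched from trial start so pre-onset
movements are caught; latency is onset minus target onset; initial hand
acceleration is averaged over the first 100 ms after target onset;
initial direction is the angle, measured from the vertical midline with
rightward positive, of the vector from the start position to the cursor
position at peak 2-D acceleration magnitude; endpoint error is the
absolute horizontal cursor–target distance when the cursor first reaches
the target's vertical position, and movement time runs from interception
onset to that crossing. Trials are excluded for blinks during target
motion, saccades overlapping the ±50 ms ASEM epoch, movement onset before
target motion, or latency above 500 ms; no lower latency bound is imposed
because onset timing was predictable in the task and genuinely short
latencies are informative.

## Psychometric layer

Condition × coherence means per participant are fitted with

$$\mathrm{ASEMvel}(x) = \frac{a}{2}\left(1 + \mathrm{erf}\frac{x-\mu}{\sigma\sqrt{2}}\right) + b,
\qquad
\mathrm{Latency}(x) = c\, e^{-(x-\mu)^2/2\sigma^2} + d,$$

with $a$ the sigmoid height (the condition contrast of interest), $b$ the
lower asymptote, $c$ the latency peak over the constant offset $d$.
Nine-point nonlinear fits are initialization-sensitive, so the fitter
(Levenberg–Marquardt via `minpack.lm`) restarts from a grid of
$\mu \in \{-0.2, 0, 0.2\}$ × $\sigma \in \{0.1, 0.3\}$ (plus
negative-amplitude starts for the Gaussian) under bounds
$\sigma \in (10^{-3}, 2]$, $|\mu| \le 1$, and keeps the best residual sum
of squares. $r^2 = 1 - SS_{res}/SS_{tot}$ is reported as computed
(negative values are possible for pathological fits and are not hidden);
flat data are returned unconverged rather than fitted. The tests pin the
fitter against a profile grid-search oracle that exploits the model's
linearity in $(a, b)$ given $(\mu, \sigma)$.

For the distributional question — does the eye reflect the *categorical*
decision (bimodal velocity distribution) or graded confidence (unimodal
shift)? — ASEM velocities are z-normalized per participant across all of
that participant's trials, pooled, and summarized as cumulative frequency
curves per condition × coherence. Unimodality is checked with a kernel
density mode count; this is a deliberate, simple surrogate for formal dip
statistics, adequate for the pooled group sizes the design produces.

## Statistical layer

Condition contrasts on fitted parameters use paired t tests. Both
`cohens_d` conventions are reported: $d_z$ (mean over SD of differences,
consistent with the t statistic) and $d_{av}$ (mean difference over the
average condition SD), since published within-subject effect sizes often
follow the latter. Other interception properties go through a two-way
repeated-measures ANOVA (condition × coherence) on per-cell participant
means, with Holm-corrected pairwise post hocs for significant effects;
effects with zero sum of squares are reported as $F = 0$, $p = 1$ rather
than NaN. Sphericity correction is not applied by default (the ANOVA is a
secondary screen here); the cell means are returned so users can apply
their preferred correction.

The central model compares three candidates for trial-level latency on
direction-signed ASEM velocity: correlated random intercept + slope per
participant, random intercept only, and fixed effects only. All are fitted
by **maximum likelihood, not REML**, because the candidates differ in
random-effects structure and the fixed-only model has no REML analogue;
BIC $= -2\log L + k\log n_{obs}$ is then comparable across all three. The
selected model's fixed slope is reported with its SE and a t test on
$n_{obs} - 2$ residual degrees of freedom (matching the convention of
quoting $t_{n-2}$ for a model with intercept and slope). Marginal and
conditional $r^2$ (variance of fixed-effect predictions, and of fitted
values, over total variance) are both reported because a bare "model
$r^2$" is ambiguous for mixed models. Per-participant intercepts and
slopes come from the random-slope model's conditional modes; simple
per-participant OLS regressions and their Pearson correlations with mean
latency quantify individual differences, and an upper-vs-lower 20%
contrast (per participant × coherence cell, control condition, floor
count with minimum 1, ties broken by trial order) provides a
selection-based check that does not lean on the regression model.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design: 10 participants × 2
conditions × 9 coherences × 20 trials, eye at 1 kHz, cursor at 60 Hz,
8 deg/s target. Participant-level parameters are drawn from configurable
populations; per trial, true ASEM velocity is the participant's sigmoid
at the trial's coherence plus trial noise (SD 0.3 deg/s), and true
latency is $\beta_{0i} + \beta_{1i} v_{signed} + \varepsilon$ with
$\beta_1 \sim \mathcal{N}(-0.03, 0.01)$ s per deg/s and residual SD
50 ms, floored at 50 ms.

Choices where the design was open:

* **Anticipation profile.** Velocity ramps linearly from 300 ms before
  onset (the gap duration) and *plateaus at the trial's true ASEM
  velocity from 150 ms before onset through the pursuit latency*. The
  plateau spans the whole ±50 ms measurement window, so with zero noise
  the measured ASEM velocity equals the generated value — the
  generative-identity tests rely on this. Pursuit then approaches target
  velocity first-order (100 ms latency, 120 ms time constant).
* **Sigmoid population.** Heights $a_{control} = 0.85 \pm 0.15$ and
  $a_{gap} = 1.60 \pm 0.20$ deg/s with baseline $b = -0.45$ were chosen
  so the direction-signed ASEM velocities come out near 0.27 (control)
  and 0.50 deg/s (gap), the magnitudes typical of gap-paradigm
  anticipation at these coherences.
* **Mediated coupling only.** The latency model includes a
  Gaussian-of-coherence component $c_i e^{-(x-\mu)^2/2\sigma^2}$ whose
  default amplitude is **zero**: by default the coherence dependence of
  latency arises entirely through the eye ($\beta_1 v$), which is the
  causal structure the analysis is designed to detect. The peaked
  latency-vs-coherence curve still emerges because $v_{signed}(x)$ is
  minimal at zero coherence. Setting $c > 0$ plants an unmediated
  pathway; because that pathway is correlated with ASEM velocity, it
  biases the single-predictor LME slope — a useful robustness probe, but
  not the default. A corollary: the simulated gap-minus-control latency
  difference is only $\beta_1 \Delta v \approx -7$ ms, smaller than
  real-data gap effects, which include pathways this generator does not
  model.
* **Independent intercepts and slopes.** $\beta_{0i}$ and $\beta_{1i}$
  are drawn independently, so cross-participant correlations between
  slope (or $r^2$) and mean latency hover near zero in synthetic data;
  the generator makes no claim about that empirical structure.
* **Reach shape.** Reaches are minimum-jerk and overshoot the target's
  vertical position by 15% ("shoot through" instruction), timed so the
  crossing coincides with the target's position; only onset timing feeds
  the headline analyses. Onset detection at the 1 deg/s criterion lags
  the true reach start by ~10–25 ms (threshold crossing plus 60 Hz
  sampling); the lag is near-constant so coupling slopes are unaffected.
* **Events and violations.** Incidental saccades (0.2/s, 1–4 deg,
  20–50 ms) avoid the ASEM epoch and incidental blinks precede target
  motion, so clean trials are not excluded; `violation_rate` plants the
  four excludable behaviors (blink during motion, epoch saccade,
  pre-onset movement, latency > 500 ms) in a stated fraction of trials
  for testing the exclusion bookkeeping.
* **Noise.** Eye and cursor noise are white velocity noise (0.2 and
  0.1 deg/s SD) integrated into position. This emulates the smooth jitter
  of fixational drift; it does not emulate microsaccades, pupil-size
  artifacts, tracker dropout, or tremor, so passing recovery tests bounds
  algorithmic error, not robustness to every hardware artifact.

Problem sizes in the test suite are scaled to the laptop-class budgets a
package check should respect: generative-identity checks use 2–10
participants at 2 trials per cell, the full-design recovery test uses one
10 × 360 cohort, detector/oracle agreement uses 200 two-second traces,
and the type-I-error study uses 500 replicates of 10 × 90 trials at the
trial-table level (the replicate loop exercises the inference layer;
trace synthesis adds nothing to that question).

## Numerical notes and limitations

* Filtering pads by odd reflection (about 6 time constants, minimum 50
  samples) so constants are preserved to machine precision and edge
  transients stay out of the analysis windows.
* Central differences are exact for quadratics; the two boundary samples
  use one-sided differences and are never inside an analysis window.
* The saccade detector's interval logic (seed on the joint criterion,
  grow to the velocity criterion) labels a few more samples than the
  strict per-sample conjunction — by design, since mid-saccade
  acceleration crosses zero; the tests quantify agreement with the
  per-sample scan at ≥ 99%.
* `fit_lme_candidates` flags singular random-effects fits rather than
  hiding them; with zero residual noise `lme4` converges with warnings
  that are suppressed deliberately in that degenerate regime.
* BIC model selection at slope SDs near the per-participant measurement
  error (≈ 0.007 s per deg/s at 360 trials) is genuinely marginal: the
  expected deviance gain from the random slope is comparable to the
  $2\log n$ penalty, so selection outcomes near that boundary vary by
  seed. This is a property of BIC, not of the implementation.
* The exclusion rules assume the mask marks blinks; trackers that emit
  sentinel positions instead need a reader-side conversion to the mask.
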