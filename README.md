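# anticept

Analysis of **anticipatory smooth eye movements (ASEMs) and manual
interception**. When the direction of upcoming target motion is cued by a
random-dot motion (RDM) stimulus with signed coherence
`x ∈ {−0.64, …, +0.64}`, the eyes begin to drift in the expected
direction before the target appears. `anticept` implements the full
analysis chain for experiments that test whether this oculomotor
anticipation speeds up interceptive hand movements:

1. **Preprocessing** — zero-phase 2nd-order Butterworth filtering (eye
   position 15 Hz, eye velocity/acceleration 30 Hz, cursor 20 Hz),
   central-difference differentiation, saccade detection (velocity >
   30 deg/s jointly with |acceleration| > 1000 deg/s²), desaccading by
   linear interpolation, blink detection from the missing-sample mask.
2. **Per-trial features** — ASEM velocity (mean horizontal desaccaded
   velocity in the ±50 ms window around target motion onset),
   interception onset (first cursor sample above 1 deg/s), latency,
   initial hand accelerations/direction, endpoint error, movement time;
   exclusion of trials with motion-epoch blinks, ASEM-epoch saccades,
   pre-onset movements, or latency > 500 ms.
3. **Psychometrics** — per participant and condition, least-squares fits
   of the cumulative Gaussian
   `ASEMvel(x) = a/2·(1 + erf((x−μ)/(σ√2))) + b`
   and the latency Gaussian
   `Latency(x) = c·exp(−(x−μ)²/2σ²) + d`,
   plus pooled per-participant z-normalized velocity distributions.
4. **Inference** — paired t tests with Cohen's d on the fitted height
   `a` and offset `d`; two-way repeated-measures ANOVA (condition ×
   coherence) with Holm post hocs; three linear mixed-effects candidates
   for `latency ~ signed ASEM velocity` (correlated random
   intercept+slope, random intercept, fixed-only) fitted by ML and
   compared by BIC; per-participant regressions, their correlations with
   mean latency, and an upper-vs-lower 20% ASEM-velocity contrast.
5. **Synthetic cohorts** — `simulate_cohort()` generates the full study
   design (10 participants × 2 conditions × 9 coherences × 20 trials;
   1 kHz eye, 60 Hz cursor, 8 deg/s target) with known ground truth,
   planted saccades/blinks, and an optional fraction of excludable
   trials, so every stage is testable without any recorded data.
   `generate_rdm_frames()` reproduces the three-interleaved-sets RDM
   update rule for the stimulus itself.

## Worked example

```r
library(anticept)

cfg    <- simulation_config(n_participants = 4, trials_per_cell = 8, seed = 7)
cohort <- simulate_cohort(cfg)
report <- run_pipeline(cohort)
print(report)
```

```
<asem_report>  config 73275f8c
  trials: 576, retained 575 (99.8%)
  exclusions: latency_over_500ms=1
  sigmoid height contrast: paired t(3) = -5.424, p = 0.0123, d_z = -2.712, d_av = -2.885, mean diff = -0.6317
  latency offset contrast: paired t(3) = 0.382, p = 0.728, d_z = 0.191, d_av = 0.285, mean diff = 0.07303
LME comparison (interception latency ~ ASEM velocity), n = 575
                  model k   logLik       BIC singular
 random_slope_intercept 6 908.3801 -1778.634     TRUE
       random_intercept 4 908.2000 -1790.983    FALSE
             fixed_only 3 764.1575 -1509.252    FALSE
best: random_intercept; fixed slope -0.0183 +/- 0.0046 s/(deg/s), t(573) = -4.01, p = 6.84e-05
```

Reading the output: one of 576 simulated trials drew a latency above the
500 ms criterion and was excluded. The sigmoid height `a` is larger in
the gap condition than in control (mean paired difference −0.63 deg/s in
control-minus-gap ordering, `t(3) = −5.42`) — releasing fixation
amplifies anticipatory velocity at identical coherence. The three
mixed-model candidates show a negative coupling: each extra deg/s of
direction-signed anticipatory velocity predicts an ~18 ms earlier
interception (`slope −0.0183 s per deg/s`). At this small cohort size the
random-intercept model wins BIC (the random-slope fit is singular); at
the full 10 × 360 design with heterogeneous slopes the random
intercept+slope model attains minimum BIC, as `run_pipeline` on
`simulation_config()` defaults shows.

Lower-level entry points (`preprocess_eye()`, `detect_saccades()`,
`compute_asem_velocity()`, `fit_cumulative_gaussian()`,
`fit_lme_candidates()`, …) expose every stage individually;
`write_cohort()` / `read_cohort()` persist cohorts as CSV traces plus a
JSON manifest, and `write_report()` exports the results tables.

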