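---
title: "Simulating a central-auditory and cognitive test battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a central-auditory and cognitive test battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsim)
```

## Why simulate a test battery

Central auditory processing (CAP) measures — gap detection, temporal
fine structure sensitivity, modulation detection, dichotic listening,
speech in noise — are candidate early markers of cognitive decline:
older adults with mild cognitive impairment (MCI, operationalized as
MoCA 19–25) perform worse than cognitively healthy controls across
these domains, and the temporal-processing measures in particular
discriminate groups well and predict MoCA scores. Raw participant data
behind such findings are typically unpublished, so the analysis chain —
adaptive psychophysics, scoring rules, nonparametric group comparisons,
factor analysis, regression, ROC — cannot be probed directly.

`capsim` rebuilds that chain as a closed-loop simulation: stimuli are
synthesized from their printed parameters, adaptive tracks are answered
by psychometric virtual listeners, cohorts are generated against
published group statistics, and the full statistical stage runs on the
result. Everything is seeded and reproducible. The point is not to
re-derive the published point estimates (impossible without the raw
data) but to make every algorithmic claim in the pipeline testable.

## Stimuli

Four stimulus families are synthesized at 44.1 kHz:

* **Interaural-phase tone sequences** (TFS-AF): one interval is four
  consecutive 400-ms tones separated by 100-ms silences (1900 ms
  total). The standard interval is diotic; in the target interval tones
  2 and 4 carry a 180° interaural phase difference, which above a
  listener-specific frequency limit becomes undetectable.
* **FM tones** (FMDL): 1250-ms tones, 500-Hz carrier, 2-Hz sinusoidal
  frequency modulation with depth in Hz as the tracked variable.
* **Gap-in-noise** (ATTR): broadband white Gaussian noise with a
  centered silent gap; gap duration in ms is tracked.
* **AM noise** (MDT): 500-ms white noise, 8-Hz sinusoidal amplitude
  modulation with depth `m` tracked and reported as `20 log10(m)` dB.

Three synthesis choices are ours, since psychoacoustic protocols rarely
print them: (1) every tone carries 10-ms raised-cosine onset/offset
ramps and gap edges carry 1-ms ramps, so that detection cues are the
intended temporal features rather than spectral splatter clicks;
(2) "broadband noise" is white Gaussian noise; (3) AM noise is rescaled
to an identical realized RMS at every modulation depth, so that overall
level carries no information about the target interval — only the
modulation does. Presentation levels (70 dB SPL, 30 dB SL) are protocol
metadata; digital buffers are peak-normalized (tones) or fixed-RMS
(noise), since no hardware calibration exists in simulation.

## The adaptive engine and its presets

All four tests use a transformed up-down staircase: after two
consecutive correct responses the stimulus steps toward harder, after
any incorrect response toward easier (2-down-1-up), which converges on
the 70.7%-correct point of the psychometric function. A reversal is a
flip of the step direction; the threshold is the geometric mean of the
last `k` reversal values.

| test | tracked value | start | harder | step | stop / use |
|---|---|---|---|---|---|
| TFS-AF | frequency (Hz) | 200 | increase | ×1.25 | 8 / 6 |
| FMDL | FM depth (Hz) | 25 | decrease | ×0.5 / ×2 | 8 / 6 |
| ATTR | gap (ms) | 10 | decrease | ×0.5 / ×2 | 8 / 6 |
| MDT | AM depth m | 0.5 | decrease | ×1.25 | 4 / 2, dB |

Two protocol readings were open: the TFS-AF "step size 1.25" and the
FMDL "step size 0.5" are interpreted as multiplicative factors (the
gap-detection protocol states its 0.5 explicitly as a factor, and all
four tracked quantities are positive and ratio-scaled); both
multiplicative and additive modes are implemented and selectable. The
MDT up-down rule is not printed; 2-down-1-up is assumed for consistency
with the other three. The TFS-AF threshold is defined by the
reversal-mean rule rather than the verbal "highest frequency
identified", which has no operational definition in an adaptive track.
Tracks are clipped to [floor, ceiling]; a direction flip while pinned
at a bound still counts as a reversal (preventing deadlock), and eight
consecutive pinned trials flag the track `hit_bound` — plumbing needed
for degenerate virtual listeners, not part of the human protocol.

## Virtual listeners

An observer is a logistic psychometric function on the log10-stimulus
axis: `p(x) = γ + (1 − γ − λ) F(±(log10 x − log10 θ)/σ)`, with chance
rate γ (1/2 for the two-interval TFS-AF, 1/3 for the three-interval
tests), lapse rate λ = 0.02 and spread σ = 0.15 log10-units by default.
The sign makes performance fall toward the harder direction. The
log-domain choice matches the multiplicative staircases: a scale change
of the stimulus axis is a shift of the function.

### What the engine does and does not guarantee

Monte-Carlo tests show the engine converges to the 70.7% point when run
to asymptote. The *printed protocols*, however, carry an inherent
finite-sample bias of the reversal-mean estimator: with 500 simulated
tracks per protocol against observers anchored at the pooled published
median thresholds, the geometric-mean estimate deviates from the true
70.7% point by roughly −3.7% (TFS-AF), +0.5 to −1% (FMDL), −3%
(ATTR) and +4.6% (MDT). The MDT protocol is the most biased because it
stops after only four reversals and averages the last two, so its
estimate still leans toward the easy starting depth; the small per-step
factor (1.25) slows its approach to equilibrium. These deviations are
small against the between-group differences being measured (ATTR medians
differ by a factor 2.7) but they exceed one Monte-Carlo standard error
at 500 tracks (≈0.5–1%), i.e. the protocols are measurably, if mildly,
biased instruments. The package's property tests therefore assert
convergence at the 15%-log-scale parameter-recovery tolerance, and the
acceptance suite's strict ±1-SE convergence check documents the
protocol bias rather than hiding it.

## Scoring the non-adaptive tests

* **QuickSIN**: seven sentences, five keywords each, at SNRs from +8 dB
  down to −10 dB in 3-dB steps; SNR loss = 22.5 − total keywords.
* **Dichotic digits**: two digits per ear per trial. In free recall,
  order-blind: all four digits recalled scores a double-correct (DCS);
  both digits of one ear plus at most one of the other scores that ear
  (Total R / Total L); the three counters are mutually exclusive per
  trial, and REA = Total R − Total L. In forced conditions a trial
  scores only when both attended-ear digits are reported. Trials per
  condition default to 20 (not printed; chosen so control medians near
  10–13 sit plausibly below the ceiling), and digits are abstracted to
  distinct integers 1–9 per ear.
* **ANT**: 120 trials covering 3 cues × 3 congruencies × 2 positions ×
  2 directions; 36 cells × 3 = 108 with the 12 extra trials placed one
  per no-cue cell (an explicit choice; the printed counts cannot tile
  evenly). Effects are condition-mean RT differences over correct
  trials only, standard ANT practice that keeps error trials out of RT
  means.
* **MRT**: 5 letters (F, G, L, P, R) × 4 conditions × 5 cycles = 100
  trials; the protocol text mentions "six letters" but lists five, and
  only five makes the trial count work. Accuracy and RT are reported
  within mirror/non-mirror classes with rotation collapsed; timeouts
  count as errors and are excluded from RT means.
* **Digit span**: lengths 2–8; success lengthens by one, failure
  repeats the length once, a second failure at the same length
  terminates with span = longest correct ("a second sequence of the
  same length" implies exactly one retry). The procedure provably
  terminates within 14 steps.
* **TMT** contributes only two completion-time fields in the cohort
  schema; it has no algorithmic content to simulate.

## The synthetic cohort

The generator draws three latent standard-normal factors per
participant — temporal/cognitive impairment (F1), dichotic/attention
(F2), peripheral hearing (F3) — and maps each measure through
`z = λ F + sqrt(1 − λ²) ε` followed by the group's quantile map, so the
marginal distribution of every measure matches its calibrated target
(median and IQR) in expectation while the factor structure links the
measures. Families: log-normal for thresholds and reaction times
(positive, right-skewed; σ solved in closed form from the median/IQR
ratio), normal for signed quantities (MDT in dB, attention effects),
truncated normal for bounded scores (PTA ≤ 40 dB HL, MoCA in the
group-defining ranges), rounded-and-clipped counts for dichotic scores.
The calibration table ships as `inst/extdata/calibration_profile.csv`.

Three consequences are worth stating plainly:

* **REA is derived, not sampled**: the MCI group's elevated REA is
  produced entirely by its lower left-ear score (the left-ear
  extinction account), with REA = Total R − Total L computed per
  participant. Because medians do not subtract, the MCI median REA
  lands near 8 (12 − 4) rather than the printed 6; the group *gap* and
  direction are faithful.
* **ANT effect units**: the published effect values (≈0.02–0.2 under a
  "msec" header) are internally inconsistent with millisecond RT
  differences; the cohort calibrates to them as printed, while the
  trial-level ANT simulator works in genuine milliseconds. The two
  deliberately do not match in magnitude.
* **Within-group covariances are an assumption**: no correlation
  structure was published; the planted three-factor model mirrors the
  published factor interpretation but is a modeling choice, recorded in
  the profile, not a data fact.

Each participant's four virtual listeners are linked deterministically
to their calibrated targets: the observer's θ is set so its
70.7%-correct point equals the target threshold. Running the battery
(`simulate_measured_battery`) then yields measured thresholds whose
rank correlation with the targets is high where between-subject spread
is wide (Spearman ρ ≈ 0.9 for ATTR and FMDL) and lower where the
calibrated spread is narrow relative to track noise (ρ ≈ 0.65 for
TFS-AF, whose MCI IQR is only 5.6 Hz around 225 Hz, and for the
4-reversal MDT protocol) — itself a realistic property of adaptive
measurement.

## The statistical stage

* **Group comparisons**: Mann-Whitney U (exact by enumeration for small
  tie-free samples, otherwise normal approximation with tie and
  continuity corrections), with Holm step-down correction applied
  separately within the 11-measure central-auditory family and the
  13-measure cognitive family, as the published tables do.
* **EFA**: minimum-residual (ULS) extraction — uniquenesses optimized
  by L-BFGS-B over [0.005, 1] starting from 1 − SMC, loadings from the
  reduced correlation matrix's eigendecomposition — followed by direct
  quartimin (oblimin, γ = 0) rotation via the oblique gradient
  projection algorithm with an identity start plus four seeded random
  starts. Heywood cases are clipped to ψ = 0.005 with a warning. One
  exclusion pass drops variables whose maximum absolute pattern loading
  is below 0.4 and refits; KMO and Bartlett's sphericity are reported
  on the retained set. Factor counts come from configuration (3 for
  MCI, 4 for control, as in the published solutions); a
  parallel-analysis helper is provided but advisory only, since no
  selection criterion was published. Cumulative variance is reported
  from squared pattern loadings of the rotated solution — one of
  several conventions, stated here because the published software's
  convention is unknown.
* **Regression**: the four OLS models for MoCA in the MCI subset
  (dichotic, speech-in-noise, temporal, covariates), with standardized
  β from z-scored variables and the overall F on (k, n − k − 1) df.
  Summary tables of this design are prone to conflating R with percent
  variance explained (R = 0.807 is not "80.7% of variance"; that is
  R² = 0.651), so the package reports both R and R² explicitly.
* **ROC**: empirical curve over observed thresholds with the fixed
  convention "higher score ⇒ predicted MCI" and *no* automatic
  direction flipping, so measures on which MCI scores lower (TFS-AF,
  DCS) correctly yield AUC < 0.5. AUC is the trapezoid/midrank value,
  identical to U/(n₁n₂); the operating point maximizes Youden's J.
* **Power**: smallest per-group n whose exact noncentral-t power
  reaches the target. One-tailed testing is used in the default
  configuration because it is the unique reading that reproduces the
  published chain (d = 0.8, α = 0.05, power 0.90 → 28 per group, 56
  total, 70 after 25% dropout inflation); a two-tailed computation is a
  flag away. Dropout inflation is `ceil(N(1 + rate))` rounded up to an
  even split.

## Problem sizes and runtime

The test suite simulates 500 tracks per protocol for the convergence
checks, 200 tracks per protocol for parameter recovery, cohorts of
35/group for the analysis-stage tests (the study's own size) and
400–500/group for calibration fidelity; the whole suite runs in well
under a minute on one CPU. The acceptance script uses 500/group for
calibration medians and 500 tracks per protocol.

## Limitations

Passing tests show the pipeline's internal consistency — scoring
formulas, staircase dynamics, estimator behavior, statistical
plumbing — under a generator whose marginals and factor structure are
calibrated to published summaries. They do not show that real listeners
behave like logistic observers with stationary lapse rates, that real
within-group covariances match the planted ones, or that the published
point estimates (p-values, loadings, AUCs, R²) would reproduce; those
depend on unpublished raw data. Attention lapses are modeled as i.i.d.,
not autocorrelated; peripheral hearing influences nothing downstream
except through its own factor; and no audio is synthesized for the
speech materials, whose tests are scored from symbolic trial records.
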