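---
title: "Modeling and analyzing dyadic keystroke synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analyzing dyadic keystroke synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duetsync)
```

## The problem

When two pianists play a duet, each must keep their own part accurate
while staying synchronized with the other — a balance the sensorimotor
synchronization literature describes as *self-other integration versus
segregation*. The paradigm implemented here probes that balance with a
2 × 2 within-dyad design: two pianists play two-phrase chorales (7
quarter notes per hand per phrase at a 120 bpm joint tempo, followed by
a two-bar pause and a second phrase at a cued tempo), while two factors
vary per trial:

* **TEMPO congruency** — each player is separately cued to speed up
  (150 bpm) or slow down (96 bpm) in the second phrase. When the cues
  conflict (incongruent), anticipation of the opposing tempo change
  already perturbs first-phrase timing, inducing millisecond-scale
  interpersonal asynchronies.
* **Motor FAMILIARITY** — whether a player has practiced the partner's
  part. Familiarity lets a player predict the partner's timing from
  their own motor repertoire, whose idiosyncrasies do not exactly match
  the partner's, shifting the balance toward segregation.

`duetsync` provides (i) a generative simulator of this paradigm, (ii)
the behavioral trial-exclusion and metric pipeline, (iii) the
repeated-measures inference layer, and (iv) a Monte Carlo estimator of
cluster-extent thresholds for voxelwise statistical maps. The numbered
scripts under `analysis/` run these stages as a workflow.

## The generative model

Each player `i` is a linear first-order phase-correcting timekeeper — the
standard coupling model in the tapping and ensemble literature. The
simulator makes no mechanistic claim about real pianists; it exists so
that every downstream stage can be exercised, calibrated and
power-analyzed on data with a known ground truth.

Onsets of phrase 1 (notes `n = 1..7`, first note nominally at 3,000 ms =
1,000 ms cue + 4 metronome beats) follow

```
T_i(n)   = tau + kappa * (tau*_i - tau) * (n / 7) + delta_i
t_i(n+1) = t_i(n) + T_i(n) - alpha_i * (t_i(n) - t_j(n)) + eta_i(n)
```

where `tau = 500` ms is the base interval, `tau*_i` is the cued
second-phrase interval (400 or 625 ms), and:

* `alpha_i` — the phase-correction gain: the fraction of the current
  asynchrony `t_i(n) - t_j(n)` corrected on the next keystroke. The
  accompanist's gain exceeds the melody player's
  (`alpha_bass > alpha_melody`), reproducing the observed asymmetry in
  which the accompanist adapts more (lag +1 cross-correlations above
  lag −1).
* `kappa * (tau*_i - tau) * (n/7)` — a linear anticipation ramp toward
  the cued tempo. With conflicting cues the two ramps diverge, producing
  the incongruency effect on mean absolute asynchrony. Any monotone ramp
  would do; the linear one is analytically tractable (a closed-form
  recursion that the tests evaluate independently).
* `delta_i ~ N(0, sigma_fam^2)`, drawn once per trial per player in
  familiar trials only — a "timing signature" offset standing in for
  reliance on one's own internal model of the partner's part. It makes
  familiar-trial asynchronies drift within a trial, raising their SD.
* `eta_i(n) ~ N(0, sigma_timekeeper^2 + sigma_motor^2)` — central and
  peripheral noise folded into one Gaussian increment per interval. The
  full two-source decomposition with its lag-1 covariance signature is
  deliberately out of scope.
* In familiar–incongruent trials only, `alpha_melody` is multiplied by
  `(1 - lambda_seg)`: the melody player partially disengages from the
  partner's conflicting timing (self-other segregation), which lowers
  the lag −1 cross-correlation in FI relative to FC while leaving the
  unfamiliar conditions untouched.

Phrase 2 (nominal onset 11,000 ms) is uncoupled — the players are muted
there — and evolves at `tau*_i` plus noise. Trials can be injected with
a wrong pitch (±1 semitone), a wrong second-phrase tempo (one player
stays at 500 ms), or an outlier first-phrase interval (×0.5 or ×1.8),
with per-trial probabilities; an injection log records the ground truth
for QC validation.

### Default parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha_melody` | 0.15 | – | melody phase-correction gain |
| `alpha_bass` | 0.30 | – | accompanist gain (larger: adapts more) |
| `lambda_seg` | 0.5 | – | melody gain reduction in FI trials |
| `kappa` | 0.04 | – | anticipation ramp gain |
| `sigma_timekeeper` | 10 | ms | central timing noise per interval |
| `sigma_motor` | 8 | ms | motor implementation noise |
| `sigma_fam` | 6 | ms | familiar-trial timing-signature SD |
| `sigma_start` | 15 | ms | first-onset jitter |
| `p_wrong_note` | 0.05 | – | wrong-pitch injection rate |
| `p_mistempo` | 0.03 | – | wrong-tempo injection rate |
| `p_outlier` | 0.01 | – | outlier-interval injection rate |

These values place the simulated group statistics in the empirically
reported regime — mean absolute asynchronies of a few ms with the
incongruent conditions a millisecond or two above the congruent ones,
within-trial asynchrony SDs in the high teens of ms with familiar above
unfamiliar, accompanist-dominant adaptation, and roughly two thirds of
trials surviving QC. They are calibration anchors, not fitted estimates;
all are overridable through `dyad_params()`.

### Randomness and reproducibility

One root seed governs a dataset. Each trial draws from its own substream
(derived from the seed and the trial counter), so changing the number or
order of trials does not change the realization of any given trial, and
`simulate_trial()` reproduces any dataset trial exactly from its
substream. Internally the per-trial noise is drawn as a fixed-layout
block, which lets `simulate_dataset()` run the coupled recursion
vectorized across trials while remaining bit-identical to the per-trial
path (injected trials are replayed through the scalar path).

## The analysis pipeline

**QC** (`run_qc()`) applies, in order: wrong-note exclusion against the
piece scores; tempo goodness of fit, excluding trials in which either
player's six second-phrase IKIs fit a non-instructed constant template
(400/625/500 ms) strictly better in mean squared error; an optional
`technical_error` metadata column (such failures are recorded, not
detected); and pooled IKI outlier trimming — all first-phrase IKIs of the
surviving trials, both players, are pooled, and any trial containing an
IKI strictly outside the pooled 1st/99th percentiles is removed whole.

Numerical choices worth stating: percentiles use linear interpolation
between order statistics (`quantile` type 7), since at a 1% cut the
convention visibly moves the bound; exact MSE ties keep the trial when
the instructed tempo is among the tied minima (only a *demonstrably*
better-fitting wrong tempo excludes); the outlier stage warns and skips
below 100 pooled IKIs; and re-running QC with the first pass's frozen
bounds is idempotent.

**Metrics** (`condition_summary()`): signed asynchronies (melody minus
bass, positive = melody later) are mean-centered within
participant-session × piece × keystroke-position cells, pooling all
instruction types — this removes piece/position difficulty without
leaking information between dyads, and leaves the between-instruction
anticipation effects intact. Accuracy is the absolute value of the
instruction-type mean asynchrony (signed means first, then absolute,
then conditions as the average of their two instruction types; the
per-trial-absolute alternative is available via `trial_means_first`,
identical under balanced retention). Stability is the per-trial SD
(n − 1) of the centered series, averaged per condition. Adaptation is
the per-trial Pearson correlation of the two players' six IKIs at lags
0/±1 with the melody (MR) player as reference — lag −1 pairs
`(melody_n, bass_{n-1})`, i.e. how much the MR player follows the
partner — Fisher z-transformed (r clipped to ±(1 − 1e−12)), averaged per
condition, with zero-variance trials treated as missing rather than
zero. The unit of analysis is the pianist, attributed to the session in
which they played in the scanner, giving 2 participants per pair.

**Inference** (`rm_anova()`, `paired_t()`, `pearson_cor()`,
`fisher_z_compare()`): with every factor at 2 levels, each
within-participant effect reduces to a single paired contrast, so
`F(1, n−1) = t²` is exact, sphericity is moot, and
`eta_p2 = F / (F + n − 1)`. The implementation is contrast-based and is
verified in the tests against an independent `aov()` sum-of-squares
decomposition to 1e−9 on 200 random balanced designs. Cohen's d is
`d_z = t/sqrt(n)`; the Fisher comparison of two correlations treats them
as independent and reports both one- and two-tailed p (the one-tailed
value is what a printed P of 0.028 at z = −1.909 corresponds to). Where
the comparison's sample size is not recorded, n = 37 per group is the
default, flagged as an inference.

**Cluster-extent Monte Carlo** (`estimate_extent_threshold()`): i.i.d.
standard normal volumes are smoothed by a separable Gaussian kernel
(σ = FWHM/(2√(2 ln 2)) per axis in voxel units) whose rows are scaled to
unit L2 norm — so every voxel keeps exactly unit variance and kernel
truncation introduces no edge bias — then re-standardized empirically
and thresholded one-tailed at `qnorm(1 − voxel_p)`. The largest
connected suprathreshold cluster per iteration (default 18-connectivity,
configurable 6/18/26; components via a voxel-adjacency graph) yields the
empirical max-cluster distribution, and the reported extent is the
smallest integer k with exceedance probability below the FWE target —
minimality that the tests assert directly. The full rectangular grid is
used (no mask).

## What the simulator does and does not emulate

Passing tests establish that the pipeline recovers the directional
effect structure from data with known ground truth; they do not certify
the model as a mechanism for real duet timing. Known divergences:

* The anticipation ramp adds within-trial spread in incongruent trials,
  so the simulator shows a small TEMPO effect on asynchrony SD that real
  pianists did not show.
* Per-trial lag ±1 correlations estimated from 5 IKI pairs are extremely
  noisy (Fisher z SD ≈ 0.7); the simulated lag −1 condition means sit
  closer to zero than empirical ones. The familiarity × tempo modulation
  of lag −1 adaptation is therefore a small effect at the default gains:
  clearly detectable in large two-sample tests (thousands of trials per
  cell), but with power well below 50% at 38 participants × 32
  trials/condition. The package documents this calibration property
  rather than inflating the default gains.
* No expressive dynamics (velocity), pedaling, polyphony, tempo
  curvature within phrases, or BOLD simulation.

## Problem sizes used by the test suite

Chosen so each check has adequate statistical power: the directional
effect tests use 4,800 trials per condition (the smallest effect, lag −1
segregation, needs ≈ 3,600/cell at α = 0.01); type-I calibration uses
1,000 replicate null datasets of 38 participants × 4 trials/condition;
power checks use 200 replicates of the full 38 × 32 design; coupling
monotonicity uses 4,032 trials per gain value; the Monte Carlo checks
run a 64³ grid at 300 iterations and 32³ grids at 200 iterations, with
the paradigm-scale 102 × 102 × 66 grid at 1,000 iterations reserved for
`analysis/05_cluster_mc.R` and `scripts/acceptance.R`.

## Limitations

The rmANOVA is deliberately restricted to fully-within 2-level
factorials (exact, oracle-checkable); unbalanced or multi-level designs
belong to `aov`/mixed-model territory. MIDI support covers Standard MIDI
File formats 0/1, note-on/off and tempo changes only. The Fisher
comparison assumes independent samples; comparing dependent correlations
is out of scope.
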