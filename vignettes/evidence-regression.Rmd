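---
title: "Within-trial decision-evidence regression: models, designs and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-trial decision-evidence regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evreg)
```

## The task and its ideal observer

The package analyzes a two-alternative forced-choice task in which a single
white dot jumps to a new random screen position every 100 ms. Positions are
drawn from a 2D Gaussian centered on one of two targets at (±25, 0) pixels
with isotropic SD 70 px; the observer must report which target is the
center of the dot cloud, within a 2.5 s deadline (at most 25 dot frames).

Because the targets are mirror-symmetric about the vertical axis, the
Gaussian likelihood ratio after `k` dots depends on the data only through
the sum of x-coordinates: all y-terms and quadratic terms cancel, leaving

$$\mathrm{logodds}_k = \frac{2\,\mu}{\sigma^2} \sum_{i \le k} x_i + b,$$

with $\mu$ = 25 px, $\sigma$ = 70 px and $b$ a participant-level bias
(default 0; its magnitude is a free parameter, exposed as `prior_bias`).
`evidence_series()` therefore defines *momentary evidence* as the signed
x-coordinate, *accumulated evidence* as its running sum, and carries the
log odds alongside; the two are exactly proportional when the bias is
constant, which is the property the analyses rely on.

## The stimulus generator

`build_stimulus_set()` reproduces the task's construction rules: `n_long`
base sequences each expanded into 6 variants that differ only in the
fifth dot's x-coordinate (−160, −96, −32, 32, 96, 160 px — a large, regular
mid-trial variation that gives across-trial regressions a strong known
source of variance), plus `n_catch` easy catch sequences; the whole set is
duplicated by mirroring every x-coordinate, which balances the set across
responses exactly. Defaults (28, 72) give 2 × (28·6 + 72) = 480 trials.

Two deliberate deviations from a strict re-enactment:

- The original long-RT and catch stimuli were *selected* from a prior
  experiment's response-time distribution and are not available; the
  generator samples fresh sequences from the same law and carries the role
  as a tag. Downstream structure (variant sextets, mirroring, interleaving)
  is preserved, but selection-induced quirks — e.g. an unusually weak
  fourth dot in the long-RT set — are not, so contrasts that depended on
  the selection (such as the dot-4 vs dot-5 choice-correlation difference)
  need not match in sign.
- "Randomly interleaved" presentation is implemented as a seeded
  constrained shuffle that forbids runs of more than 4 long-RT-derived
  trials (a plain shuffle is used for compositions too catch-poor to
  satisfy the constraint). Any statistic that depends on presentation
  order — only the trial-counter nuisance regressor does — should be robust
  to this choice.

## Simulated behavior

`simulate_decision()` is a discrete-time bounded accumulator: per 100 ms
frame the state gains `x_k` plus `Normal(0, acc_noise_sd)`; the response is
the sign of the state at the first crossing of ±`bound`, at time
`k·100 + ndt_ms`; trials that never cross time out (choice 0) and are
excluded from all response-dependent analyses. Human parameters are
unavailable, so `acc_noise_sd`, `bound` and `ndt_ms` are free calibration
parameters; the defaults (60 px, 215 px, 300 ms) were chosen once, from the
standard diffusion approximations, to put behavior in a realistic band for
this kind of task — intermediate accuracy (70–85%) and sub-timeout median
response times — and `check_calibration()` verifies the band rather than
any human value. Under the defaults the simulated observer reaches ~79%
accuracy with a median RT of 800 ms and ~2% timeouts on the 480-trial set.

## The signal generator and what it does (not) emulate

`simulate_session()` produces a trials × channels × samples tensor at 10 ms
resolution spanning −300..2500 ms around first-dot onset. It contains:

1. the embedded effects: for an `effect_spec(regressor, lag_ms, weights,
   amplitude)`, the channel-weighted, amplitude-scaled z-value of the
   regressor of the dot that is "lagged-active" at each sample — a dot
   contributes only while displayed, only if shown before the response,
   and only before the response itself;
2. a condition-independent evoked template (damped 10 Hz oscillation,
   identical across trials), which per-slice z-scoring/intercepts must
   absorb — a built-in check that average responses cannot leak into
   correlation estimates;
3. white Gaussian noise.

With a z-scored regressor and noise SD $s$, the theoretical signal-regressor
correlation at the embedded latency is $a/\sqrt{a^2+s^2}$;
`amplitude_for_correlation()` inverts this, which is how ground-truth
recovery targets are set. Note the frame-length persistence: a lag-L effect
is present from L to L+90 ms after its dot's onset, so recovered latency
profiles plateau over that span rather than peaking at a single sample.

Not emulated: realistic MEG noise spectra, gradiometer/magnetometer sensor
physics, head movement, artifacts, and any forward/inverse source mixing —
"area-level" inputs are simply tensors whose channel axis carries area
labels (`parcellation_labels()` supplies a synthetic 362-row label table,
180 generic area codes per hemisphere plus one unassigned collection each;
`channel_layout()` a synthetic 102-position layout). Passing tests
therefore validate the statistical machinery, not robustness to structured
noise or source leakage.

## The three regression designs

**Normalization contract.** Signals are z-scored across trials *within*
each (channel, time) slice, before any concatenation; regressors are
z-scored *after* concatenation, on the assembled design matrix; intercepts
are untouched. This asymmetry is deliberate and preserved: it makes a
single-regressor coefficient exactly the Pearson correlation (asserted to
1e-10 in the tests) and multi-regressor coefficients approximate partial
correlations. The pooled response vector of an expanded design need not
have SD exactly 1 — slices are heterogeneous — and that is allowed.

**Expanded design.** For latency t from dot onset, a trial with response
time rt contributes dot k when `(k−1)·100 < rt`, `s < rt`, and
`s < rt − 200` with `s = (k−1)·100 + t`. Both inequalities are strict: a
sample exactly 200 ms before the response is excluded, which reproduces
the documented example (rt 880 ms, t 120 ms: 9 dots shown, 8 candidate
samples, 6 retained). Regressors: evidence (current x, or the running sum
in the accumulated variant), y, |x|, |y|, per-coordinate perceptual updates
|coord_k − coord_{k−1}|, previous-dot accumulated sums, intercept. The
response is deliberately absent (constant within trial). Two conventions
the construction itself leaves open were fixed as follows: the update at
dot 1 is referenced to the screen center (the dot appears from a central
fixation display), so `update(1) = |coord_1|`; and updates are
per-coordinate absolute differences, not Euclidean, since x- and y-updates
enter as separate variables.

On the previous-sum regressor: writing S = P + x for the full and previous
sums, residualizing S on x equals residualizing P on x — an exact identity
the tests verify at 1e-12 — so the previous-sum and orthogonalized-full-sum
designs span the same model. P itself, however, is *not* exactly the
orthogonalized S: pooling left- and right-target trials induces a genuine
correlation (~0.15 under the task's stimulus law, since both P and x scale
with the target), and the tests accordingly check closeness (r > 0.95)
rather than identity.

**Standard design.** One row per non-timeout trial; x/y of the first 6
dots as interest regressors (12 columns), response, within-participant
trial counter and intercept as nuisance. Whether timed-out trials should
enter was left open by the construction; they are excluded, consistent
with the other designs.

**Response-aligned design.** Choice (−1/+1, z-scored), trial-time (scaled
to unit SD but not centered — the one exception to full z-scoring) and
intercept. The univariate grid defaults to 70 points spanning −500..190 ms
around the response (the grid length is fixed by convention; the exact
window is configurable); trials whose shifted sample falls outside the
recorded epoch are dropped at that time point and the remaining trials are
re-z-scored, keeping the within-time-point contract.
`run_window_aggregate()` stacks all samples of a window (build-up
−500..−120 ms, response −30..100 ms) into one regression per channel.

## Second-level inference

`second_level()` runs the summary-statistics approach: per cell, a
two-sided one-sample t-test across participants (dof n−1) on the
first-level coefficients. Zero across-participant variance is handled
without overflow (t = ±Inf, p = 0; or t = 0, p = 1 for an all-zero cell);
cells missing for any participant (too few rows at late latencies) stay
missing and are excluded from correction rather than imputed.
`fdr_correct()` applies Benjamini–Hochberg jointly over the full flattened
time × location grid — 70 × 362 = 25,340 hypotheses for the default
area-level dot-aligned grid — via `stats::p.adjust`; the test suite checks
it against an independently coded step-up. Default levels follow the
use-case: α = 0.01 for momentary-evidence maps, α = 0.05 for accumulated
(whose between-participant variability is higher), both configurable.

One statistical point worth recording: under the global null with
independent p-values the BH procedure attains E[FDP] = α *exactly* (Simes'
equality), so a finite-replicate check "mean FDP ≤ α" is a coin flip. The
calibration tests therefore bound the Monte-Carlo mean by
α + 2·sqrt(α(1−α)/n_rep); this bound was fixed before any measurement.

Displays follow the convention of rectifying after averaging:
`grand_average_magnitude()` returns the mean over channels of the absolute
across-participant mean coefficient (≤ the average of rectified values,
strictly when signs mix), plus the signed topography.
`significant_windows()` extracts maximal contiguous significant time
intervals with locations ranked by time-averaged |t|.

## Pattern differences between windows

`normalize_pattern()` shifts a spatial magnitude vector so its subset
minimum is 0 (ties at the minimum map to exactly 0) and scales so the
subset mean is 1; parameters come from the reference subset but apply to
all locations. The transform is invariant to positive rescaling, so
`compare_windows()` — first-level normalized differences (window B minus
A), second-level t per location, BH across locations at α = 0.01 — is
blind to global amplitude changes and isolates pattern shape. At the
area level the normalization subset is each window's significant
locations and only locations significant in at least one window are
tested (an empty union is an error). The first-level magnitude is |β|
from the window-aggregated fit (the per-time-averaged alternative can be
fed in instead, as the function takes plain magnitude matrices). A caveat
inherent to mean-1 normalization: a localized boost slightly depresses
normalized values everywhere else (by boost·k/n_loc on average), so
"only the cluster is flagged" holds when that redistribution is small
against between-participant variability — the regime the defaults target.

## Behavioral analysis

`choice_evidence_correlation()` computes per-participant, per-dot Pearson
correlations between signed choices and momentary or accumulated
coordinates over non-timeout trials, with zero-variance cells returned as
NA (never silently 0). `dot_influence_anova()` treats participant × dot
cells as independent observations in a one-way ANOVA across dots — with
34 participants and 14 dots this gives dof (13, 462); correlations enter
untransformed by default (a Fisher transform can be applied to the table
beforehand). `paired_dot_ttest()` compares two dots across participants
(dof n−1). Mirror antisymmetry — mirroring all stimuli and flipping all
choices leaves every correlation unchanged — is covered by a property test.

## Problem sizes and numerical choices

Test and acceptance runs use the full 480-trial stimulus geometry but small
channel counts (1–8), cohorts of 2–34, and, for calibration Monte-Carlos,
direct simulation of first-level coefficient grids (34 participants,
40 × 70 cells, 100–200 replicates) — sizes chosen so the whole suite runs
in well under a minute per module while keeping every estimate's
Monte-Carlo error far below the asserted tolerances. OLS is solved by QR;
rank deficiency is an error naming the collinear columns. Overlapping
expanded-design rows are serially dependent within trials; coefficients
are still OLS (no GLS correction), matching the design's definition — a
known limitation that standard errors at the first level inherit, and one
reason inference happens only at the second level.
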