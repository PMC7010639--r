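# evreg — event-related regression of decision evidence in neural time series

`evreg` implements a within-trial decision-evidence regression pipeline for
event-stream neural recordings (MEG-like sensor or cortical-area signals
sampled at 100 Hz). It is aimed at researchers studying perceptual decision
making with rapidly updating stimuli: a single dot jumps to a new random
position every 100 ms, its horizontal coordinate carries the evidence for a
left/right choice, and the question is *when* and *where* the measured
signals follow the trial-by-trial ups and downs of that evidence.

Because no public dataset accompanies this design, the package pairs the
analysis with a full synthetic-data generator — stimuli, bounded-accumulator
behavior, and signal tensors with embedded ground-truth effects — so every
stage can be validated against known truth.

## The model

**Evidence.** For a dot sequence with coordinates (x_k, y_k) drawn from a 2D
Gaussian centered on one of two horizontally symmetric targets (±25 px,
SD 70 px), the ideal observer's momentary evidence is the signed
x-coordinate and its accumulated evidence is the running sum. The log
posterior odds of the two targets after k dots reduce to

    logodds_k = (2 * mean_px / sd_px^2) * sum(x_1..x_k) + prior_bias,

so the cumulative sum is an (almost perfectly correlated) stand-in for the
model-based evidence. y-coordinates are decision-irrelevant and serve as a
perceptual control variable.

**Event-related regression.** First-level coefficients come from OLS fits of
z-scored signals on z-scored regressors, making each coefficient an
approximate partial correlation. Three designs are implemented:

- *standard*: one row per trial, regressors x_1..x_6, y_1..y_6 plus
  response, trial counter and intercept, fitted per channel and time point;
- *expanded*: one row per (trial, dot) pair at a fixed latency from each
  dot's onset, with samples later than 200 ms before the response excluded
  (for a response at 880 ms and latency 120 ms this keeps 6 of 8 candidate
  samples from the 9 presented dots); regressors are the momentary evidence
  (or the running sum in the accumulated variant), the y-coordinate, and
  nuisance terms (absolute coordinates, perceptual updates, previous-dot
  accumulated sums);
- *response-aligned*: per-trial choice (−1/+1) and trial-time regressors on
  data re-referenced to each trial's response, as a univariate grid and as
  window-aggregated fits (build-up −500..−120 ms, response −30..100 ms).

**Inference.** Second-level two-sided t-tests across participants per
(regressor, location, time) cell, Benjamini–Hochberg FDR over the whole
time × location grid (70 × 362 = 25,340 cells for the default area-level
grid), permutation-over-trials null baselines, grand-average magnitude time
courses, and a shift-and-scale normalized spatial-pattern difference test
between time windows.

## Worked example

```r
library(evreg)

stimuli  <- build_stimulus_set(seed = 1)        # 28 long-RT base x 6 variants + 72 catch, mirrored
outcomes <- simulate_behavior(stimuli, seed = 2)
check_calibration(outcomes)[c("accuracy", "median_rt_ms")]
#> $accuracy      0.792
#> $median_rt_ms  800

# embed a known momentary-evidence effect at 120 ms latency, correlation 0.1
a      <- amplitude_for_correlation(0.1, 1)
eff    <- effect_spec("x", lag_ms = 120, weights = c(1, 0), amplitude = a)
tensor <- simulate_session(stimuli, outcomes, effects = list(eff),
                           n_channels = 2, seed = 3)

fl <- run_expanded(tensor, stimuli, outcomes)   # 70 latencies, 0..690 ms
b  <- fl$beta["x", 1, ]
fl$times[which.max(abs(b))]                     #> 200   (within the 120..210 ms plateau)
b[fl$times == 120]                              #> 0.103 (analytic target 0.1)
fl$n_rows[fl$times == 120]                      #> 3134  rows pooled across trials
```

The simulated observer sits at 79% accuracy with a 800 ms median response
time; the expanded regression recovers the embedded effect at its latency
(a lag-L effect persists while its dot is displayed, so recovery plateaus
over L..L+90 ms) and at the calibrated correlation scale. Channel 2, which
carries no effect, stays at the permutation-null level.

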