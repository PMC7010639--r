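#' Specify a ground-truth effect to embed in simulated signals
#'
#' An effect ties one evidence regressor to the signal at a fixed latency
#' from each dot's onset: while dot `k` is the dot whose processing (delayed
#' by `lag_ms`) is visible at sample time `t`, the channel `c` signal gains
#' `weights[c] * amplitude * z(regressor value of dot k)`. Amplitudes are on
#' the z-scored signal scale, so with noise SD `s` the theoretical
#' correlation between signal and regressor at the embedded latency is
#' `amplitude / sqrt(amplitude^2 + s^2)` in fully weighted channels.
#'
#' @param regressor one of `"x"`, `"y"`, `"accum_x"`, `"accum_y"`,
#'   `"accum_prev_x"`, `"accum_prev_y"`: the stimulus quantity the signal
#'   tracks (momentary coordinate, or its running sum up to / before the
#'   current dot).
#' @param lag_ms latency from dot onset, multiple of 10 ms.
#' @param weights per-channel topography weights (unitless).
#' @param amplitude effect scale (see Details above).
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(regressor, lag_ms, weights, amplitude) {
  stopifnot(regressor %in% c("x", "y", "accum_x", "accum_y",
                             "accum_prev_x", "accum_prev_y"))
  if (lag_ms %% 10 != 0) stop("lag_ms must be a multiple of 10 ms")
  if (amplitude < 0) stop("amplitude must be non-negative")
  structure(list(regressor = regressor, lag_ms = lag_ms,
                 weights = as.numeric(weights), amplitude = amplitude),
            class = "effect_spec")
}

#' Amplitude that yields a target signal-regressor correlation
#'
#' Inverts the analytic relation `r = a / sqrt(a^2 + noise_sd^2)` for a unit
#' variance (z-scored) regressor.
#'
#' @param r target Pearson correlation (0 <= r < 1).
#' @param noise_sd signal noise SD.
#' @return amplitude `a`.
#' @export
amplitude_for_correlation <- function(r, noise_sd = 1) {
  stopifnot(r >= 0, r < 1)
  noise_sd * r / sqrt(1 - r^2)
}

# per-(trial, dot) regressor values on the full stimulus set, z-scored over
# all entries (the embedding scale is global, like the design-matrix contract)
regressor_values <- function(stimuli, regressor) {
  x <- stim_matrix(stimuli, "x")
  y <- stim_matrix(stimuli, "y")
  val <- switch(regressor,
    x = x,
    y = y,
    accum_x = t(apply(x, 1, cumsum)),
    accum_y = t(apply(y, 1, cumsum)),
    accum_prev_x = cbind(0, t(apply(x, 1, cumsum))[, -ncol(x), drop = FALSE]),
    accum_prev_y = cbind(0, t(apply(y, 1, cumsum))[, -ncol(y), drop = FALSE]),
    stop("unknown regressor: ", regressor)
  )
  (val - mean(val)) / stats::sd(val)
}

#' Simulate one participant's signal tensor
#'
#' Generates a trials x channels x samples tensor at 10 ms resolution with
#' time zero at first dot onset, spanning `-300..2500` ms. The signal is the
#' sum of (i) the embedded ground-truth effects, (ii) a condition-independent
#' evoked template (damped 10 Hz oscillation, identical across trials, which
#' downstream analyses must absorb via the intercept / per-slice centering),
#' and (iii) white Gaussian noise. A dot contributes to an effect only while
#' it is the lagged-active dot, only if it was shown before the response, and
#' only before the response itself.
#'
#' @param stimuli a `stimulus_set`.
#' @param outcomes outcome data.frame, one row per trial (same order).
#' @param effects list of [effect_spec()] objects (may be empty).
#' @param noise_sd white noise SD.
#' @param n_channels number of channels; defaults to the 102-magnetometer
#'   grid. Effect weights must match this length.
#' @param evoked_amplitude amplitude of the evoked template (0 disables).
#' @param participant_id identifier stored in the tensor.
#' @param seed optional RNG seed.
#' @return a `signal_tensor`: list with `data` (array trials x channels x
#'   samples), `time_ms`, `t0_index`, `sample_ms` (10), `baseline_span`
#'   (-300, 0), `channel_ids`, `participant_id`.
#' @export
simulate_session <- function(stimuli, outcomes, effects = list(),
                             noise_sd = 1, n_channels = 102,
                             evoked_amplitude = 0.5,
                             participant_id = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_trials <- length(stimuli$sequences)
  stopifnot(nrow(outcomes) == n_trials)
  time_ms <- seq(-300, 2500, by = 10)
  n_samp <- length(time_ms)
  for (ef in effects) {
    if (!inherits(ef, "effect_spec")) stop("effects must be effect_spec objects")
    if (length(ef$weights) != n_channels)
      stop("effect weight map must cover all ", n_channels, " channels")
  }

  dat <- array(stats::rnorm(n_trials * n_channels * n_samp, sd = noise_sd),
               dim = c(n_trials, n_channels, n_samp))

  if (evoked_amplitude > 0) {
    tm <- pmax(time_ms, 0)
    evoked <- evoked_amplitude * exp(-tm / 200) * sin(2 * pi * 10 * tm / 1000)
    evoked[time_ms < 0] <- 0
    dat <- dat + rep(evoked, each = n_trials * n_channels)
  }

  dur <- stimuli$dot_duration_ms
  max_dots <- length(stimuli$sequences[[1]]$x)
  rt <- outcomes$rt_ms
  rt[outcomes$timed_out] <- stimuli$timeout_ms
  for (ef in effects) {
    zval <- regressor_values(stimuli, ef$regressor)  # trials x dots
    for (si in seq_len(n_samp)) {
      t <- time_ms[si]
      k <- floor((t - ef$lag_ms) / dur) + 1
      if (k < 1 || k > max_dots) next
      # dot must have been shown and the sample must precede the response
      active <- ((k - 1) * dur < rt) & (t < rt)
      if (!any(active)) next
      contrib <- ef$amplitude * zval[, k]
      contrib[!active] <- 0
      dat[, , si] <- dat[, , si] + outer(contrib, ef$weights)
    }
  }

  structure(list(participant_id = participant_id, data = dat,
                 time_ms = time_ms, sample_ms = 10,
                 t0_index = which(time_ms == 0),
                 baseline_span = c(-300, 0),
                 channel_ids = sprintf("MAG%03d", seq_len(n_channels))),
            class = "signal_tensor")
}

#' Baseline-correct a signal tensor
#'
#' Subtracts, per trial and channel, the mean signal in the baseline window
#' (default -300..0 ms from first dot onset).
#'
#' @param tensor a `signal_tensor`.
#' @return the corrected tensor.
#' @export
baseline_correct <- function(tensor) {
  span <- tensor$baseline_span
  idx <- which(tensor$time_ms >= span[1] & tensor$time_ms < span[2])
  if (length(idx) == 0) stop("baseline window not covered by tensor")
  bl <- apply(tensor$data[, , idx, drop = FALSE], c(1, 2), mean)
  tensor$data <- tensor$data - as.vector(bl)  # recycles over samples
  tensor
}

#' Simulate a cohort of participants
#'
#' Each participant gets their own stimulus presentation (same stimulus set),
#' simulated behavior, and a signal tensor whose effect amplitudes are drawn
#' from `Normal(template amplitude, between_sd)` (truncated at 0), giving the
#' second-level analyses true between-participant variability. Per-participant
#' seeds are derived deterministically from `seed`.
#'
#' @param stimuli a `stimulus_set` shared by the cohort.
#' @param n_participants cohort size (>= 2).
#' @param effects template list of [effect_spec()].
#' @param between_sd SD of per-participant amplitude deviations.
#' @param noise_sd,n_channels,evoked_amplitude passed to [simulate_session()].
#' @param acc_noise_sd,bound,ndt_ms accumulator parameters for behavior.
#' @param seed cohort seed.
#' @return list with `tensors` (list of `signal_tensor`), `outcomes`
#'   (list of outcome data.frames) and `amplitudes` (list of numeric vectors,
#'   the realized per-participant effect amplitudes), one element per
#'   participant.
#' @export
generate_cohort <- function(stimuli, n_participants = 34, effects = list(),
                            between_sd = 0, noise_sd = 1, n_channels = 102,
                            evoked_amplitude = 0.5,
                            acc_noise_sd = 60, bound = 215, ndt_ms = 300,
                            seed = NULL) {
  if (!is_count(n_participants) || n_participants < 2)
    stop("n_participants must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_participants)
  tensors <- vector("list", n_participants)
  outcomes <- vector("list", n_participants)
  amplitudes <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed(sub_seeds[p])
    out <- simulate_behavior(stimuli, acc_noise_sd = acc_noise_sd,
                             bound = bound, ndt_ms = ndt_ms)
    eff_p <- lapply(effects, function(ef) {
      ef$amplitude <- max(0, stats::rnorm(1, ef$amplitude, between_sd))
      ef
    })
    amplitudes[[p]] <- vapply(eff_p, `[[`, numeric(1), "amplitude")
    tensors[[p]] <- simulate_session(stimuli, out, effects = eff_p,
                                     noise_sd = noise_sd,
                                     n_channels = n_channels,
                                     evoked_amplitude = evoked_amplitude,
                                     participant_id = p)
    outcomes[[p]] <- out
  }
  list(tensors = tensors, outcomes = outcomes, amplitudes = amplitudes)
}

#' @export
print.signal_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("signal_tensor: participant %s, %d trials x %d channels x %d samples (%d..%d ms)\n",
              x$participant_id, d[1], d[2], d[3],
              min(x$time_ms), max(x$time_ms)))
  invisible(x)
}
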