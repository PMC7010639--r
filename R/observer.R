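#' Momentary and accumulated evidence for one trial
#'
#' In this task the ideal observer's momentary evidence is the signed
#' x-coordinate of each dot, and accumulated evidence is the running sum of
#' x-coordinates. The y-coordinates and the symmetric targets drop out of
#' the posterior: only horizontal position separates the alternatives.
#'
#' @param seq_ a `dot_sequence`.
#' @param mean_px,sd_px Gaussian task parameters used for the log-odds scale.
#' @param prior_bias additive log-odds offset representing an overall bias
#'   toward one alternative (0 = unbiased).
#' @return list with per-dot vectors: `momentary` (= x), `accumulated`
#'   (prefix sums), `accumulated_prev` (prefix sums shifted, leading 0), and
#'   `logodds` (ideal-observer log posterior odds right vs. left).
#' @export
#' @examples
#' s <- list(x = c(-160, 96, 32), y = c(0, 0, 0))
#' class(s) <- "dot_sequence"
#' evidence_series(s)$accumulated  # -160 -64 -32
evidence_series <- function(seq_, mean_px = 25, sd_px = 70, prior_bias = 0) {
  acc <- cumsum(seq_$x)
  prev <- c(0, acc[-length(acc)])
  list(momentary = seq_$x,
       accumulated = acc,
       accumulated_prev = prev,
       logodds = log_posterior_odds(seq_, k = seq_along(seq_$x),
                                    mean_px = mean_px, sd_px = sd_px,
                                    prior_bias = prior_bias))
}

#' Ideal-observer log posterior odds
#'
#' Log posterior odds of the right vs. left target after observing dots
#' `1..k`, under the generative model of the task (2D Gaussian around either
#' target, equal priors up to `prior_bias`). Because the targets are
#' symmetric about the vertical axis, the y-coordinates and all quadratic
#' terms cancel and the log odds reduce to a linear function of the
#' cumulative sum of x-coordinates:
#' `logodds = (2 * mean_px / sd_px^2) * sum(x[1:k]) + prior_bias`.
#'
#' @param seq_ a `dot_sequence`.
#' @param k dot index (may be a vector) up to which evidence is integrated.
#' @param mean_px,sd_px task Gaussian parameters; `sd_px` must be positive.
#' @param prior_bias log prior odds offset.
#' @return log posterior odds, same length as `k`.
#' @export
log_posterior_odds <- function(seq_, k, mean_px = 25, sd_px = 70,
                               prior_bias = 0) {
  if (!is.numeric(sd_px) || sd_px <= 0) stop("sd_px must be positive")
  stopifnot(all(k >= 1), all(k <= length(seq_$x)))
  sums <- cumsum(seq_$x)[k]
  (2 * mean_px / sd_px^2) * sums + prior_bias
}

#' Simulate one decision with a bounded accumulator
#'
#' A discrete-time drift-diffusion stand-in for a participant: at each
#' 100 ms frame the accumulator adds the momentary evidence `x[k]` plus
#' Gaussian noise; a response is emitted with the sign of the state when its
#' magnitude reaches `bound`, at time `k * 100 + ndt_ms`. If the bound is
#' not reached within the frame budget the trial times out (choice 0).
#'
#' @param seq_ a `dot_sequence`.
#' @param acc_noise_sd accumulator noise SD per 100 ms step, in pixels.
#' @param bound decision bound in accumulated pixels; must be positive.
#' @param ndt_ms non-decision time added to the crossing time.
#' @param timeout_ms trial deadline from first dot onset.
#' @return one-row data.frame: `trial_id`, `choice` (-1/+1, 0 on timeout),
#'   `rt_ms`, `timed_out`, `correct` (vs. the generating target; NA on
#'   timeout).
#' @export
simulate_decision <- function(seq_, acc_noise_sd = 60, bound = 215,
                              ndt_ms = 300, timeout_ms = 2500) {
  if (!is.numeric(bound) || bound <= 0) stop("bound must be positive")
  if (ndt_ms < 0) stop("ndt_ms must be non-negative")
  n <- length(seq_$x)
  state <- 0
  choice <- 0L
  rt <- NA_real_
  for (k in seq_len(n)) {
    state <- state + seq_$x[k] +
      if (acc_noise_sd > 0) stats::rnorm(1, 0, acc_noise_sd) else 0
    if (abs(state) >= bound) {
      choice <- if (state >= 0) 1L else -1L
      rt <- k * 100 + ndt_ms
      break
    }
  }
  timed_out <- choice == 0L || rt > timeout_ms
  if (timed_out) {
    choice <- 0L
    rt <- timeout_ms
  }
  data.frame(trial_id = seq_$trial_id, choice = choice, rt_ms = rt,
             timed_out = timed_out,
             correct = if (timed_out) NA else choice == seq_$target)
}

#' Simulate behavior for a whole stimulus set
#'
#' Runs [simulate_decision()] on every sequence of a stimulus set.
#'
#' @param stimuli a `stimulus_set`.
#' @param acc_noise_sd,bound,ndt_ms accumulator parameters, see
#'   [simulate_decision()].
#' @param seed optional RNG seed.
#' @return data.frame of trial outcomes, one row per trial in presentation
#'   order (columns as in [simulate_decision()]).
#' @export
simulate_behavior <- function(stimuli, acc_noise_sd = 60, bound = 215,
                              ndt_ms = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(stimuli$sequences, simulate_decision,
                acc_noise_sd = acc_noise_sd, bound = bound, ndt_ms = ndt_ms,
                timeout_ms = stimuli$timeout_ms)
  do.call(rbind, out)
}

#' Check accumulator calibration against target behavior bands
#'
#' Summarizes simulated behavior and checks it against configured bands for
#' accuracy and median RT. The bands describe plausible task performance
#' under moderate time pressure (intermediate accuracy, sub-timeout RTs);
#' they are a sanity gate for free accumulator parameters, not an assertion
#' about any particular participant population.
#'
#' @param outcomes outcome data.frame from [simulate_behavior()].
#' @param accuracy_band inclusive accuracy bounds on non-timeout trials.
#' @param median_rt_band_ms inclusive bounds on the median RT (ms).
#' @return list with `accuracy`, `median_rt_ms`, `timeout_rate`,
#'   and logical `within_bands`.
#' @export
check_calibration <- function(outcomes, accuracy_band = c(0.70, 0.85),
                              median_rt_band_ms = c(500, 1500)) {
  ok <- !outcomes$timed_out
  acc <- mean(outcomes$correct[ok])
  med <- stats::median(outcomes$rt_ms[ok])
  list(accuracy = acc, median_rt_ms = med,
       timeout_rate = mean(outcomes$timed_out),
       within_bands = acc >= accuracy_band[1] && acc <= accuracy_band[2] &&
         med >= median_rt_band_ms[1] && med <= median_rt_band_ms[2])
}
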