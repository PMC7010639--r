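#' Configuration for the expanded regression design
#'
#' @param variant `"momentary"`: evidence regressor is the current dot's
#'   x-coordinate, with the sum of all previous x-coordinates as a separate
#'   nuisance regressor. `"accumulated"`: the evidence regressor is the sum
#'   of x-coordinates up to and including the current dot, and the
#'   previous-sum regressor is dropped.
#' @param exclusion_ms samples this close to (or after) the response are
#'   excluded, to keep motor activity out of stimulus-aligned estimates.
#' @param dot_duration_ms frame duration.
#' @param max_dots maximum dots per trial.
#' @param nuisance include the nuisance regressors (absolute coordinates,
#'   perceptual updates, accumulated-previous sums).
#' @param drop_zero_variance drop zero-variance columns (with a message)
#'   instead of raising an error.
#' @return a `design_config` list.
#' @export
design_config <- function(variant = c("momentary", "accumulated"),
                          exclusion_ms = 200, dot_duration_ms = 100,
                          max_dots = 25, nuisance = TRUE,
                          drop_zero_variance = FALSE) {
  variant <- match.arg(variant)
  if (exclusion_ms < 0) stop("exclusion_ms must be >= 0")
  structure(list(variant = variant, exclusion_ms = exclusion_ms,
                 dot_duration_ms = dot_duration_ms, max_dots = max_dots,
                 nuisance = nuisance,
                 drop_zero_variance = drop_zero_variance),
            class = "design_config")
}

#' Select the rows of an expanded design
#'
#' For one time-from-dot-onset, lists the (trial, dot) pairs whose lagged
#' sample enters the expanded regression. A trial with response time `rt`
#' contributes dot `k` when: the dot was shown (`(k-1)*100 < rt`), its lagged
#' sample `s = (k-1)*100 + t_from_onset_ms` precedes the response (`s < rt`),
#' and the sample clears the pre-response exclusion (`s < rt - exclusion_ms`,
#' strict, so a sample exactly at the exclusion boundary is removed).
#' Timed-out trials contribute no rows.
#'
#' For example, with `rt = 880`, `t_from_onset_ms = 120` and the default
#' 200 ms exclusion: 9 dots were shown (onsets 0..800 ms), 8 lagged samples
#' precede the response, and 6 rows survive the exclusion (dots 1-6).
#'
#' @param outcomes outcome data.frame (`trial_id`, `rt_ms`, `timed_out`).
#' @param t_from_onset_ms time from dot onset, multiple of 10 ms, >= 0.
#' @param cfg a [design_config()].
#' @return data.frame with columns `trial_id`, `dot_index`,
#'   `sample_time_ms` (from first dot onset).
#' @export
build_expanded_rows <- function(outcomes, t_from_onset_ms,
                                cfg = design_config()) {
  if (t_from_onset_ms < 0) stop("t_from_onset_ms must be >= 0")
  if (t_from_onset_ms %% 10 != 0)
    stop("t_from_onset_ms must be on the 10 ms grid")
  dur <- cfg$dot_duration_ms
  keep <- !outcomes$timed_out
  res <- lapply(which(keep), function(i) {
    rt <- outcomes$rt_ms[i]
    k <- seq_len(cfg$max_dots)
    onset <- (k - 1) * dur
    s <- onset + t_from_onset_ms
    sel <- onset < rt & s < rt & s < rt - cfg$exclusion_ms
    if (!any(sel)) return(NULL)
    data.frame(trial_id = outcomes$trial_id[i], dot_index = k[sel],
               sample_time_ms = s[sel])
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0)
    return(data.frame(trial_id = integer(), dot_index = integer(),
                      sample_time_ms = numeric()))
  do.call(rbind, res)
}

#' Build the expanded design matrix
#'
#' Assembles the regressor matrix for one expanded regression. Regressors of
#' interest are the evidence term (current x, or the running sum in the
#' accumulated variant) and the current y; nuisance regressors are the
#' absolute coordinates, the per-coordinate perceptual updates
#' `|coord_k - coord_{k-1}|` (dot 1 referenced to screen center, so
#' `update(1) = |coord_1|`), the accumulated-previous sums, and an intercept.
#' The response is deliberately absent: the expanded design models
#' within-trial fluctuations while the response is constant within a trial.
#'
#' All non-intercept columns are z-scored after concatenation across rows
#' (the normalization that makes coefficients approximate correlations).
#' A zero-variance column raises an error naming the column, unless the
#' config says to drop it.
#'
#' @param stimuli a `stimulus_set`.
#' @param rows row table from [build_expanded_rows()].
#' @param cfg a [design_config()].
#' @return list with `X` (rows x regressors matrix, named columns, intercept
#'   last), `rows`, `cfg`.
#' @export
build_expanded_design <- function(stimuli, rows, cfg = design_config()) {
  if (nrow(rows) == 0) stop("row set is empty")
  xm <- stim_matrix(stimuli, "x")
  ym <- stim_matrix(stimuli, "y")
  accx <- t(apply(xm, 1, cumsum))
  accy <- t(apply(ym, 1, cumsum))
  i <- cbind(rows$trial_id, rows$dot_index)
  iprev <- cbind(rows$trial_id, pmax(rows$dot_index - 1, 1))
  first <- rows$dot_index == 1

  x_k <- xm[i]; y_k <- ym[i]
  prev_x <- ifelse(first, 0, accx[iprev])
  prev_y <- ifelse(first, 0, accy[iprev])
  upd_x <- abs(x_k - ifelse(first, 0, xm[iprev]))
  upd_y <- abs(y_k - ifelse(first, 0, ym[iprev]))

  if (cfg$variant == "momentary") {
    cols <- list(x = x_k, y = y_k)
    if (cfg$nuisance)
      cols <- c(cols, list(abs_x = abs(x_k), abs_y = abs(y_k),
                           update_x = upd_x, update_y = upd_y,
                           accum_prev_x = prev_x, accum_prev_y = prev_y))
  } else {
    cols <- list(accum_x = accx[i], y = y_k)
    if (cfg$nuisance)
      cols <- c(cols, list(abs_x = abs(x_k), abs_y = abs(y_k),
                           update_x = upd_x, update_y = upd_y,
                           accum_prev_y = prev_y))
  }

  sds <- vapply(cols, stats::sd, numeric(1))
  zero <- !is.finite(sds) | sds == 0
  if (any(zero)) {
    if (cfg$drop_zero_variance) {
      message("dropping zero-variance column(s): ",
              paste(names(cols)[zero], collapse = ", "))
      cols <- cols[!zero]
    } else {
      stop("zero-variance regressor column(s): ",
           paste(names(cols)[zero], collapse = ", "))
    }
  }
  X <- cbind(vapply(cols, zscore, numeric(nrow(rows))),
             intercept = 1)
  list(X = X, rows = rows, cfg = cfg)
}

#' Build the standard (first-dot-aligned) per-trial design
#'
#' One row per non-timeout trial; regressors of interest are the x- and
#' y-coordinates of the first `n_dots` dots (12 columns by default), with the
#' response, a within-participant trial counter and an intercept as nuisance
#' regressors. All non-intercept columns are z-scored.
#'
#' @param stimuli a `stimulus_set`.
#' @param outcomes outcome data.frame.
#' @param n_dots number of leading dots whose coordinates enter as interest
#'   regressors.
#' @return list with `X` (named columns `x_1..x_n, y_1..y_n, response,
#'   trial_counter, intercept`), `trial_id` of retained trials.
#' @export
build_standard_design <- function(stimuli, outcomes, n_dots = 6) {
  keep <- which(!outcomes$timed_out)
  if (length(keep) < 3) stop("need >= 3 non-timeout trials")
  tid <- outcomes$trial_id[keep]
  xm <- stim_matrix(stimuli, "x")[tid, seq_len(n_dots), drop = FALSE]
  ym <- stim_matrix(stimuli, "y")[tid, seq_len(n_dots), drop = FALSE]
  colnames(xm) <- sprintf("x_%d", seq_len(n_dots))
  colnames(ym) <- sprintf("y_%d", seq_len(n_dots))
  X <- cbind(xm, ym, response = outcomes$choice[keep],
             trial_counter = seq_along(keep))
  X <- apply(X, 2, zscore)
  X <- cbind(X, intercept = 1)
  list(X = X, trial_id = tid)
}

#' Build the response-aligned per-trial design
#'
#' Regressors: the signed choice (-1 left / +1 right, z-scored), trial-time
#' (the within-participant trial counter, scaled to unit SD but not
#' centered), and an intercept. Timed-out trials are excluded.
#'
#' @param outcomes outcome data.frame.
#' @return list with `X` (named columns `choice, trial_time, intercept`),
#'   `trial_id`, `rt_ms` of retained trials.
#' @export
build_response_design <- function(outcomes) {
  keep <- which(!outcomes$timed_out)
  if (length(keep) == 0) stop("all trials timed out")
  if (length(keep) < 3) stop("need >= 3 non-timeout trials")
  X <- cbind(choice = zscore(outcomes$choice[keep]),
             trial_time = unit_sd(seq_along(keep)),
             intercept = 1)
  list(X = X, trial_id = outcomes$trial_id[keep], rt_ms = outcomes$rt_ms[keep])
}

#' Z-score a signal tensor across trials within time points
#'
#' Normalizes the data to mean 0, SD 1 across trials, separately for every
#' (channel, sample) slice. In expanded regressions this is applied before
#' rows from different time points are concatenated, so the pooled response
#' vector need not have SD exactly 1 — the asymmetry with the regressor
#' normalization (which happens after concatenation) is deliberate.
#'
#' @param tensor a `signal_tensor`.
#' @return the normalized tensor (attribute `zscored` set).
#' @export
zscore_signal <- function(tensor) {
  d <- dim(tensor$data)
  if (d[1] < 2) stop("need >= 2 trials to z-score")
  m <- apply(tensor$data, c(2, 3), mean)
  s <- apply(tensor$data, c(2, 3), stats::sd)
  if (any(s == 0)) {
    bad <- which(s == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero SD across trials at channel %d, sample %d (t = %d ms)",
                 bad[1], bad[2], tensor$time_ms[bad[2]]))
  }
  for (tr in seq_len(d[1]))
    tensor$data[tr, , ] <- (tensor$data[tr, , ] - m) / s
  attr(tensor, "zscored") <- TRUE
  tensor
}
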