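#' Ordinary least squares fit
#'
#' Minimal deterministic OLS via QR. `y` may be a matrix (one fit per
#' column, shared design). Rank deficiency is an error that names the
#' collinear columns rather than silently dropping them.
#'
#' @param X design matrix with named columns; more rows than columns.
#' @param y response vector or matrix (rows match `X`).
#' @return coefficient vector (or regressors x responses matrix).
#' @export
fit_ols <- function(X, y) {
  y <- as.matrix(y)
  if (nrow(X) != nrow(y)) stop("X and y row counts differ")
  if (nrow(X) <= ncol(X)) stop("need more rows than regressors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  b <- qr.coef(qrX, y)
  rownames(b) <- colnames(X)
  if (ncol(b) == 1) drop(b) else b
}

#' Permute a signal tensor over trials
#'
#' Applies one random permutation to the trial axis, identical across
#' channels and samples, leaving stimuli and outcomes untouched. Re-running
#' a regression analysis on the permuted tensor gives the empirical null
#' level against which coefficient magnitudes are compared.
#'
#' @param tensor a `signal_tensor`.
#' @param seed optional RNG seed.
#' @return the permuted tensor.
#' @export
permute_trials <- function(tensor, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- dim(tensor$data)[1]
  if (n < 2) stop("need >= 2 trials to permute")
  tensor$data <- tensor$data[sample.int(n), , , drop = FALSE]
  tensor
}

# map sample times (ms from first dot onset) to tensor sample indices
sample_index <- function(tensor, time_ms) {
  idx <- match(time_ms, tensor$time_ms)
  if (anyNA(idx)) stop("sample time outside tensor range")
  idx
}

#' Run the expanded regression over a time-from-onset grid
#'
#' For each time from dot onset, builds the expanded row set and design, and
#' fits one OLS per channel on the concatenated (z-scored per original
#' slice) data. Times with no more rows than regressors are stored as
#' missing and excluded from group statistics downstream.
#'
#' @param tensor a `signal_tensor` (z-scored per slice on the fly if not
#'   already).
#' @param stimuli a `stimulus_set`.
#' @param outcomes outcome data.frame for this participant.
#' @param cfg a [design_config()].
#' @param times time-from-onset grid (ms), default 0..690 in 10 ms steps.
#' @return a `firstlevel_result`: list with `beta` (regressor x channel x
#'   time array), `n_rows` per time, `times`, `regressors`, `participant_id`,
#'   `design` ("expanded"), `variant`.
#' @export
run_expanded <- function(tensor, stimuli, outcomes, cfg = design_config(),
                         times = seq(0, 690, by = 10)) {
  if (!isTRUE(attr(tensor, "zscored"))) tensor <- zscore_signal(tensor)
  n_ch <- dim(tensor$data)[2]
  regs <- NULL
  beta <- NULL
  n_rows <- integer(length(times))
  for (ti in seq_along(times)) {
    rows <- build_expanded_rows(outcomes, times[ti], cfg)
    n_rows[ti] <- nrow(rows)
    if (nrow(rows) == 0) next
    des <- build_expanded_design(stimuli, rows, cfg)
    if (is.null(beta)) {
      regs <- colnames(des$X)
      beta <- array(NA_real_, dim = c(length(regs), n_ch, length(times)),
                    dimnames = list(regs, tensor$channel_ids, times))
    }
    if (nrow(des$X) <= ncol(des$X)) next  # flagged missing (NA)
    sidx <- sample_index(tensor, rows$sample_time_ms)
    Y <- matrix(NA_real_, nrow(rows), n_ch)
    for (ch in seq_len(n_ch))
      Y[, ch] <- tensor$data[cbind(rows$trial_id, ch, sidx)]
    beta[, , ti] <- fit_ols(des$X, Y)
  }
  if (is.null(beta)) stop("no time point produced any rows")
  structure(list(participant_id = tensor$participant_id, beta = beta,
                 n_rows = n_rows, times = times, regressors = regs,
                 design = "expanded", variant = cfg$variant),
            class = "firstlevel_result")
}

#' Run a per-trial regression over a time grid
#'
#' Fits, per channel and time point, an OLS of the (z-scored across trials)
#' signal on a per-trial design. With `align = "t0"` the time grid is
#' relative to first dot onset; with `align = "response"` it is relative to
#' each trial's response time, and trials whose shifted sample falls outside
#' the recorded epoch are dropped at that time point (the data are re-z-scored
#' across the retained trials, keeping the within-time-point contract).
#'
#' @param tensor a `signal_tensor`.
#' @param design design list from [build_standard_design()] or
#'   [build_response_design()].
#' @param times time grid in ms (relative to the alignment point); the
#'   response-aligned default is 70 points spanning -500..190 ms.
#' @param align `"t0"` or `"response"`.
#' @return a `firstlevel_result` (see [run_expanded()]); `n_rows` counts the
#'   trials retained per time point.
#' @export
run_pertrial <- function(tensor, design, times = NULL,
                         align = c("t0", "response")) {
  align <- match.arg(align)
  if (is.null(times))
    times <- if (align == "response") seq(-500, 190, by = 10)
             else seq(0, 690, by = 10)
  n_ch <- dim(tensor$data)[2]
  regs <- colnames(design$X)
  beta <- array(NA_real_, dim = c(length(regs), n_ch, length(times)),
                dimnames = list(regs, tensor$channel_ids, times))
  n_rows <- integer(length(times))
  if (align == "t0") {
    if (!isTRUE(attr(tensor, "zscored"))) tensor <- zscore_signal(tensor)
    sidx <- sample_index(tensor, times)
    for (ti in seq_along(times)) {
      Y <- matrix(tensor$data[design$trial_id, , sidx[ti]],
                  nrow = length(design$trial_id), ncol = n_ch)
      n_rows[ti] <- nrow(design$X)
      if (nrow(design$X) > ncol(design$X))
        beta[, , ti] <- fit_ols(design$X, Y)
    }
  } else {
    if (is.null(design$rt_ms)) stop("response alignment needs design$rt_ms")
    for (ti in seq_along(times)) {
      # nearest 10 ms sample of rt + tau, per trial
      t_abs <- round((design$rt_ms + times[ti]) / 10) * 10
      ok <- t_abs >= min(tensor$time_ms) & t_abs <= max(tensor$time_ms)
      n_rows[ti] <- sum(ok)
      if (sum(ok) <= ncol(design$X)) next
      sidx <- sample_index(tensor, t_abs[ok])
      Y <- matrix(NA_real_, sum(ok), n_ch)
      for (ch in seq_len(n_ch))
        Y[, ch] <- tensor$data[cbind(design$trial_id[ok], ch, sidx)]
      Y <- apply(Y, 2, zscore)
      beta[, , ti] <- fit_ols(design$X[ok, , drop = FALSE], Y)
    }
  }
  structure(list(participant_id = tensor$participant_id, beta = beta,
                 n_rows = n_rows, times = times, regressors = regs,
                 design = if (align == "t0") "standard" else "response",
                 variant = NA_character_),
            class = "firstlevel_result")
}

#' Window-aggregated response-aligned regression
#'
#' Concatenates the (per-time z-scored) response-aligned data from all
#' samples in a time window into one regression per channel, replicating
#' the per-trial design rows across the window's time points. Used for the
#' build-up (-500..-120 ms) and response (-30..100 ms) windows.
#'
#' @param tensor a `signal_tensor`.
#' @param design design list from [build_response_design()].
#' @param window_ms length-2 vector, window bounds in ms relative to the
#'   response, inclusive, on the 10 ms grid.
#' @return list with `beta` (regressor x channel matrix), `n_rows`,
#'   `window_ms`, `regressors`, `participant_id`.
#' @export
run_window_aggregate <- function(tensor, design, window_ms) {
  if (length(window_ms) != 2 || window_ms[1] > window_ms[2])
    stop("window_ms must be (start, end) with start <= end")
  taus <- seq(window_ms[1], window_ms[2], by = 10)
  n_ch <- dim(tensor$data)[2]
  Xs <- list(); Ys <- list()
  for (tau in taus) {
    t_abs <- round((design$rt_ms + tau) / 10) * 10
    ok <- t_abs >= min(tensor$time_ms) & t_abs <= max(tensor$time_ms)
    if (sum(ok) < 3) next
    sidx <- sample_index(tensor, t_abs[ok])
    Y <- matrix(NA_real_, sum(ok), n_ch)
    for (ch in seq_len(n_ch))
      Y[, ch] <- tensor$data[cbind(design$trial_id[ok], ch, sidx)]
    Ys[[length(Ys) + 1]] <- apply(Y, 2, zscore)
    Xs[[length(Xs) + 1]] <- design$X[ok, , drop = FALSE]
  }
  if (length(Xs) == 0) stop("window contains no usable samples")
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)
  beta <- fit_ols(X, Y)
  list(beta = beta, n_rows = nrow(X), window_ms = window_ms,
       regressors = colnames(design$X),
       participant_id = tensor$participant_id)
}

#' @export
print.firstlevel_result <- function(x, ...) {
  d <- dim(x$beta)
  cat(sprintf("firstlevel_result (%s): participant %s, %d regressors x %d channels x %d times\n",
              x$design, x$participant_id, d[1], d[2], d[3]))
  invisible(x)
}
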