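#' Second-level statistics across participants
#'
#' Summary-statistics inference: per (regressor, location, time) cell, a
#' two-sided one-sample t-test across participants on the first-level
#' coefficients, keeping the mean coefficient for topographies. Cells that
#' are missing for any participant stay missing. Zero across-participant
#' variance yields `t = +/-Inf` (or 0 when the mean is also 0) and `p = 0`
#' (or 1) without overflow.
#'
#' @param results list of `firstlevel_result` (or of bare coefficient arrays
#'   with identical dimensions), one per participant.
#' @return a `group_result`: list with arrays `mean_beta`, `t`, `p` of
#'   dimension regressor x location x time, plus `n_participants`, `times`,
#'   `regressors`.
#' @export
second_level <- function(results) {
  if (length(results) < 2) stop("need >= 2 participants")
  betas <- lapply(results, function(r)
    if (inherits(r, "firstlevel_result")) r$beta else r)
  d <- dim(betas[[1]])
  if (!all(vapply(betas, function(b) identical(dim(b), d), logical(1))))
    stop("first-level grids are misaligned across participants")
  n <- length(betas)
  arr <- array(unlist(betas), dim = c(d, n))
  m <- apply(arr, 1:3, mean)
  s <- apply(arr, 1:3, stats::sd)
  se <- s / sqrt(n)
  t <- ifelse(se == 0, ifelse(m == 0, 0, sign(m) * Inf), m / se)
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df = n - 1))
  p[t == 0 & se == 0] <- 1
  dimnames(m) <- dimnames(t) <- dimnames(p) <- dimnames(betas[[1]])
  r1 <- results[[1]]
  structure(list(mean_beta = m, t = t, p = p, n_participants = n,
                 times = if (inherits(r1, "firstlevel_result")) r1$times else NULL,
                 regressors = dimnames(m)[[1]]),
            class = "group_result")
}

#' Benjamini-Hochberg FDR correction over a grid
#'
#' Standard BH step-up applied jointly to the full flattened grid (all times
#' and all locations together). With the default dot-aligned area-level grid
#' (70 time points x 362 areas) this corrects across 25,340 hypotheses.
#' Missing p-values are excluded from the correction and flagged
#' non-significant.
#'
#' @param p numeric vector, matrix or array of p-values.
#' @param alpha FDR level.
#' @return logical significance mask with the shape of `p`.
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(as.vector(p), method = "BH")
  mask <- !is.na(adj) & adj <= alpha
  if (!is.null(dim(p))) {
    dim(mask) <- dim(p)
    dimnames(mask) <- dimnames(p)
  }
  mask
}

#' Grand-average coefficient magnitude time course
#'
#' Per time point: the mean over channels of the absolute across-participant
#' mean coefficient (rectify after averaging, the display convention for
#' sensor-level results). Also returns the signed mean-coefficient
#' topography per time point.
#'
#' @param results list of `firstlevel_result`.
#' @param regressor regressor name.
#' @param channels channel indices to average over (default all).
#' @return list with `times`, `magnitude` (per-time mean |grand-average|),
#'   `topography` (channels x times signed grand average).
#' @export
grand_average_magnitude <- function(results, regressor, channels = NULL) {
  betas <- lapply(results, function(r) r$beta[regressor, , , drop = FALSE])
  d <- dim(betas[[1]])
  arr <- array(unlist(betas), dim = c(d[2], d[3], length(betas)))
  ga <- apply(arr, 1:2, mean)  # channels x times grand average
  if (is.null(channels)) channels <- seq_len(nrow(ga))
  list(times = results[[1]]$times,
       magnitude = colMeans(abs(ga[channels, , drop = FALSE]), na.rm = TRUE),
       topography = ga)
}

#' Extract significant time windows for one regressor
#'
#' Given an FDR mask over a location x time grid, returns the maximal
#' contiguous time intervals containing at least one significant location,
#' with the per-interval locations ranked by their time-averaged |t| within
#' the interval (average over the interval's time points).
#'
#' @param mask logical location x time matrix (one regressor's slice).
#' @param t numeric location x time matrix of second-level t-values.
#' @param times time axis in ms.
#' @return list of windows, each a list with `start_ms`, `end_ms`,
#'   `locations` (data.frame `location`, `mean_abs_t`, significant locations
#'   only, sorted decreasing).
#' @export
significant_windows <- function(mask, t, times) {
  stopifnot(identical(dim(mask), dim(t)), ncol(mask) == length(times))
  any_sig <- apply(mask, 2, any, na.rm = TRUE)
  if (!any(any_sig)) return(list())
  r <- rle(any_sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (b in which(r$values)) {
    cols <- starts[b]:ends[b]
    locs <- which(apply(mask[, cols, drop = FALSE], 1, any, na.rm = TRUE))
    mt <- rowMeans(abs(t[locs, cols, drop = FALSE]), na.rm = TRUE)
    ord <- order(mt, decreasing = TRUE)
    loc_names <- rownames(mask)
    out[[length(out) + 1]] <- list(
      start_ms = times[starts[b]], end_ms = times[ends[b]],
      locations = data.frame(
        location = if (is.null(loc_names)) locs[ord] else loc_names[locs[ord]],
        mean_abs_t = mt[ord]))
  }
  out
}

#' Tidy table of group results
#'
#' @param group a `group_result`.
#' @param mask optional logical array matching the grid (FDR flags).
#' @return data.frame with regressor, location, time_ms, mean_beta, t, p
#'   (and sig when a mask is given), suitable for TSV export.
#' @export
group_to_table <- function(group, mask = NULL) {
  d <- dim(group$mean_beta)
  dn <- dimnames(group$mean_beta)
  tab <- expand.grid(regressor = dn[[1]] %||% seq_len(d[1]),
                     location = dn[[2]] %||% seq_len(d[2]),
                     time_ms = group$times %||% seq_len(d[3]),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$mean_beta <- as.vector(group$mean_beta)
  tab$t <- as.vector(group$t)
  tab$p <- as.vector(group$p)
  if (!is.null(mask)) tab$sig <- as.vector(mask)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
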