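#' Plot a coefficient magnitude time course
#'
#' Base-graphics time course of grand-average coefficient magnitudes, with
#' optional permutation-null traces drawn dotted.
#'
#' @param times time axis (ms).
#' @param magnitude magnitude trace from [grand_average_magnitude()].
#' @param null_traces optional matrix (traces in rows) of permutation
#'   baselines.
#' @param ... passed to [graphics::plot()].
#' @export
plot_magnitude_timecourse <- function(times, magnitude, null_traces = NULL,
                                      ...) {
  graphics::plot(times, magnitude, type = "l", lwd = 2,
                 xlab = "time (ms)", ylab = "mean |beta|", ...)
  if (!is.null(null_traces))
    for (i in seq_len(nrow(null_traces)))
      graphics::lines(times, null_traces[i, ], lty = 3)
  invisible(NULL)
}

#' Plot a sensor topography
#'
#' Crude 2D topography: channel positions from a layout table, colored by
#' signed coefficient value (blue negative, red positive).
#'
#' @param values per-channel values.
#' @param layout layout data.frame from [channel_layout()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_topography <- function(values, layout = channel_layout(length(values)),
                            ...) {
  stopifnot(nrow(layout) == length(values))
  sc <- values / max(abs(values), na.rm = TRUE)
  col <- grDevices::rgb(pmax(sc, 0), 0, pmax(-sc, 0))
  graphics::plot(layout$x2d, layout$y2d, pch = 21, bg = col, cex = 2,
                 asp = 1, xlab = "", ylab = "", axes = FALSE, ...)
  invisible(NULL)
}
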