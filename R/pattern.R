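#' Shift-and-scale normalization of a spatial magnitude pattern
#'
#' Normalizes a vector of correlation magnitudes so that spatial pattern
#' shape can be compared across conditions with different overall levels:
#' the minimum over a reference subset is shifted to 0 and the result is
#' scaled so its mean over the subset equals 1. Normalization parameters
#' come from the subset but are applied to all requested locations. The
#' shift keeps magnitude variance from shrinking for patterns with large
#' overall level, and the transform is invariant to positive rescaling of
#' the input.
#'
#' @param magnitudes numeric vector of per-location magnitudes.
#' @param subset indices of the locations defining the normalization
#'   parameters (default: all); at least 2, not all equal.
#' @return normalized magnitudes, same length as `magnitudes`.
#' @export
#' @examples
#' normalize_pattern(c(1, 2, 3))  # 0 1 2
normalize_pattern <- function(magnitudes, subset = seq_along(magnitudes)) {
  if (length(subset) < 2) stop("normalization subset must have >= 2 locations")
  ms <- magnitudes[subset]
  if (max(ms) == min(ms)) stop("cannot normalize constant magnitudes")
  shifted <- magnitudes - min(ms)
  shifted / mean(shifted[subset])
}

#' Compare spatial correlation patterns between two time windows
#'
#' Tests, per location, whether the normalized spatial pattern of
#' correlation magnitudes differs between two time windows. Per participant,
#' each window's magnitude pattern is normalized with [normalize_pattern()]
#' and the per-location difference (window B minus window A) is computed on
#' the first level; a two-sided one-sample t-test across participants is run
#' per location and corrected with BH-FDR at `alpha` across locations.
#'
#' At the sensor level all locations define the normalization. At the
#' area ("source") level, where most locations carry no effect, the
#' normalization parameters for each window are computed only over the
#' locations significant in that window, and differences are tested only for
#' locations significant in at least one window.
#'
#' Because the normalization is invariant to uniform scaling, a global
#' amplitude change between the windows produces zero differences: the test
#' isolates pattern shape, not level.
#'
#' @param mag_a,mag_b participants x locations matrices of first-level
#'   correlation magnitudes (|beta| from the window-aggregated fits).
#' @param mask_a,mask_b optional logical per-location significance masks for
#'   each window (source level); `NULL` means all locations (sensor level).
#' @param alpha FDR level across locations.
#' @return a `pattern_comparison` data.frame: per location, mean normalized
#'   magnitudes `norm_a`/`norm_b`, `mean_diff` (B - A), `t`, `p`, `sig`;
#'   locations outside the tested set carry NA. Attribute `tested` holds the
#'   tested location indices.
#' @export
compare_windows <- function(mag_a, mag_b, mask_a = NULL, mask_b = NULL,
                            alpha = 0.01) {
  stopifnot(identical(dim(mag_a), dim(mag_b)))
  n_p <- nrow(mag_a); n_loc <- ncol(mag_a)
  source_level <- !is.null(mask_a) || !is.null(mask_b)
  sub_a <- if (is.null(mask_a)) seq_len(n_loc) else which(mask_a)
  sub_b <- if (is.null(mask_b)) seq_len(n_loc) else which(mask_b)
  tested <- if (source_level) sort(union(sub_a, sub_b)) else seq_len(n_loc)
  if (length(tested) == 0)
    stop("no location significant in either window; nothing to compare")

  diffs <- matrix(NA_real_, n_p, n_loc)
  na_s <- nb_s <- matrix(NA_real_, n_p, n_loc)
  for (i in seq_len(n_p)) {
    na <- normalize_pattern(mag_a[i, ], sub_a)
    nb <- normalize_pattern(mag_b[i, ], sub_b)
    na_s[i, ] <- na; nb_s[i, ] <- nb
    diffs[i, tested] <- nb[tested] - na[tested]
  }
  t_val <- p_val <- rep(NA_real_, n_loc)
  for (j in tested) {
    d <- diffs[, j]
    s <- stats::sd(d)
    if (s == 0) {
      t_val[j] <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p_val[j] <- if (mean(d) == 0) 1 else 0
    } else {
      t_val[j] <- mean(d) / (s / sqrt(n_p))
      p_val[j] <- 2 * stats::pt(-abs(t_val[j]), df = n_p - 1)
    }
  }
  sig <- rep(NA, n_loc)
  sig[tested] <- fdr_correct(p_val[tested], alpha)
  res <- data.frame(location = colnames(mag_a) %||% seq_len(n_loc),
                    norm_a = colMeans(na_s), norm_b = colMeans(nb_s),
                    mean_diff = colMeans(diffs), t = t_val, p = p_val,
                    sig = sig)
  attr(res, "tested") <- tested
  class(res) <- c("pattern_comparison", "data.frame")
  res
}
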