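#' Sample one dot-sequence stimulus
#'
#' Draws a sequence of dot positions for a single trial of the evidence
#' accumulation task. Dot coordinates are sampled independently from a 2D
#' Gaussian centered on the target location `(target * mean_px, 0)` with
#' isotropic standard deviation `sd_px`. Coordinates are in pixels on a
#' screen-centered axis, x rightward-positive, y upward-positive.
#'
#' @param target `-1` (left) or `+1` (right); which target generated the trial.
#' @param n_dots number of dot positions (frames); one frame lasts 100 ms.
#' @param mean_px horizontal distance of each target from screen center.
#' @param sd_px standard deviation of the dot position Gaussian, both axes.
#' @param trial_id integer identifier carried through downstream tables.
#'
#' @return A `dot_sequence`: list with fields `trial_id`, `target`, `x`, `y`
#'   (numeric vectors of length `n_dots`), `is_catch`, `variant_value`
#'   (fifth-dot x override, or `NA`), and `mirrored`.
#'
#' @details Uses the current RNG state; call `set.seed()` for reproducibility.
#' @seealso [build_stimulus_set()] for the full experimental set.
#' @export
#' @examples
#' set.seed(1)
#' s <- sample_dot_sequence(target = 1)
#' length(s$x)
sample_dot_sequence <- function(target, n_dots = 25, mean_px = 25, sd_px = 70,
                                trial_id = 1L) {
  stopifnot(target %in% c(-1, 1))
  if (!is_count(n_dots) || n_dots < 1) stop("n_dots must be a positive integer")
  if (!is.numeric(sd_px) || sd_px < 0) stop("sd_px must be non-negative")
  seq_ <- list(
    trial_id = as.integer(trial_id),
    target = as.integer(target),
    x = stats::rnorm(n_dots, mean = target * mean_px, sd = sd_px),
    y = stats::rnorm(n_dots, mean = 0, sd = sd_px),
    is_catch = FALSE,
    variant_value = NA_real_,
    mirrored = FALSE
  )
  class(seq_) <- "dot_sequence"
  seq_
}

#' Fifth-dot variants of a base sequence
#'
#' Expands one base sequence into six variants that are identical except for
#' the x-coordinate of the fifth dot, which takes the values -160, -96, -32,
#' 32, 96, 160 pixels. The regular large variation half-way through the trial
#' gives the across-trial regressions a strong, known source of variance.
#'
#' @param base a `dot_sequence` with at least 5 dots.
#' @param values fifth-dot x values, one variant per value.
#' @return list of `dot_sequence`, one per value, `variant_value` set.
#' @export
apply_fifth_dot_variants <- function(base,
                                     values = c(-160, -96, -32, 32, 96, 160)) {
  stopifnot(inherits(base, "dot_sequence"))
  if (length(base$x) < 5) stop("base sequence must have at least 5 dots")
  lapply(values, function(v) {
    s <- base
    s$x[5] <- v
    s$variant_value <- v
    s
  })
}

#' Mirror a dot sequence across the vertical screen axis
#'
#' Negates every x-coordinate, leaves y untouched, flips the generating
#' target and toggles the `mirrored` flag. Mirroring the full stimulus set
#' balances it across responses: any choice tendency for a particular
#' sequence is cancelled by its twin.
#'
#' @param seq_ a `dot_sequence`.
#' @return the mirrored `dot_sequence`.
#' @export
mirror_sequence <- function(seq_) {
  stopifnot(inherits(seq_, "dot_sequence"))
  seq_$x <- -seq_$x
  seq_$target <- -seq_$target
  if (!is.na(seq_$variant_value)) seq_$variant_value <- -seq_$variant_value
  seq_$mirrored <- !seq_$mirrored
  seq_
}

#' Build the full stimulus set
#'
#' Constructs the task's trial set: `n_long` base sequences tagged as
#' long-RT material, each expanded into 6 fifth-dot variants, plus `n_catch`
#' easy catch sequences; the resulting set is duplicated by mirroring and
#' pseudo-randomized so that long-RT-derived trials are interleaved with
#' catch trials (no run of more than 4 consecutive long-RT-derived trials).
#' Defaults give 2 * (28 * 6 + 72) = 480 trials.
#'
#' Base sequences are sampled fresh (the class of stimuli is defined by the
#' sampling distribution); their role — long-RT-derived vs. catch — is carried
#' as a tag so downstream analyses can condition on it.
#'
#' @param n_long number of long-RT base sequences (each yields 6 variants).
#' @param n_catch number of catch sequences.
#' @param seed integer seed for sampling and ordering; `NULL` uses the
#'   current RNG state.
#' @param mean_px,sd_px Gaussian parameters passed to [sample_dot_sequence()].
#' @param n_dots dots per sequence.
#' @return a `stimulus_set`: list with `sequences` (list of `dot_sequence`
#'   in presentation order, `trial_id` 1..n), `order_seed`, `dot_duration_ms`
#'   (100), `timeout_ms` (2500), `n_long`, `n_catch`.
#' @export
#' @examples
#' ss <- build_stimulus_set(n_long = 2, n_catch = 3, seed = 1)
#' length(ss$sequences)  # 2*(2*6 + 3) = 30
build_stimulus_set <- function(n_long = 28, n_catch = 72, seed = NULL,
                               mean_px = 25, sd_px = 70, n_dots = 25) {
  if (!is_count(n_long) || n_long < 1) stop("n_long must be >= 1")
  if (!is_count(n_catch) || n_catch < 0) stop("n_catch must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  base_long <- lapply(seq_len(n_long), function(i) {
    s <- sample_dot_sequence(target = sample(c(-1L, 1L), 1),
                             n_dots = n_dots, mean_px = mean_px, sd_px = sd_px)
    s$is_catch <- FALSE
    s
  })
  variants <- unlist(lapply(base_long, apply_fifth_dot_variants),
                     recursive = FALSE)
  catches <- lapply(seq_len(n_catch), function(i) {
    s <- sample_dot_sequence(target = sample(c(-1L, 1L), 1),
                             n_dots = n_dots, mean_px = mean_px, sd_px = sd_px)
    s$is_catch <- TRUE
    s
  })
  pre_mirror <- c(variants, catches)
  full <- c(pre_mirror, lapply(pre_mirror, mirror_sequence))

  is_long <- !vapply(full, function(s) s$is_catch, logical(1))
  ord <- interleave_order(is_long, max_run = 4L)
  full <- full[ord]
  for (i in seq_along(full)) full[[i]]$trial_id <- i

  structure(list(sequences = full, order_seed = seed,
                 dot_duration_ms = 100, timeout_ms = 2500,
                 n_long = n_long, n_catch = n_catch,
                 mean_px = mean_px, sd_px = sd_px),
            class = "stimulus_set")
}

# constrained shuffle: random permutation, then repair runs of long-RT trials
# longer than max_run by swapping their surplus into random catch positions;
# compositions too catch-poor to satisfy the constraint get a plain shuffle
interleave_order <- function(is_long, max_run = 4L) {
  n <- length(is_long)
  ord <- sample.int(n)
  if (!any(is_long) || all(is_long)) return(ord)
  if (sum(is_long) > max_run * (sum(!is_long) + 1)) return(ord)
  for (pass in 1:1000) {
    flags <- is_long[ord]
    r <- rle(flags)
    bad <- which(r$values & r$lengths > max_run)
    if (length(bad) == 0) return(ord)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    catch_pos <- which(!flags)
    for (b in bad) {
      # move the element just past the allowed run to a random catch slot
      i <- starts[b] + max_run
      j <- sample(catch_pos, 1)
      tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
    }
  }
  stop("could not satisfy interleaving constraint") # nocov
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "stimulus_set: %d trials (%d long-RT base x 6 variants + %d catch, mirrored)\n",
    length(x$sequences), x$n_long, x$n_catch))
  cat(sprintf("  dot duration %d ms, timeout %d ms\n",
              x$dot_duration_ms, x$timeout_ms))
  invisible(x)
}

#' Stimulus coordinates as matrices
#'
#' @param stimuli a `stimulus_set`.
#' @param coordinate `"x"` or `"y"`.
#' @return trials x dots numeric matrix in presentation order.
#' @export
stim_matrix <- function(stimuli, coordinate = c("x", "y")) {
  coordinate <- match.arg(coordinate)
  do.call(rbind, lapply(stimuli$sequences, `[[`, coordinate))
}

#' Stimulus set as a tidy table
#'
#' One row per trial x dot, suitable for TSV export with
#' [utils::write.table()].
#'
#' @param stimuli a `stimulus_set`.
#' @return data.frame with columns trial_id, dot_index, x_px, y_px, target,
#'   is_catch, mirrored.
#' @export
stimulus_to_table <- function(stimuli) {
  rows <- lapply(stimuli$sequences, function(s) {
    data.frame(trial_id = s$trial_id, dot_index = seq_along(s$x),
               x_px = s$x, y_px = s$y, target = s$target,
               is_catch = s$is_catch, mirrored = s$mirrored)
  })
  do.call(rbind, rows)
}
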