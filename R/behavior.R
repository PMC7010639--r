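#' Per-dot correlation between choices and evidence
#'
#' For each participant and each dot index, the Pearson correlation across
#' trials between the signed choice (-1/+1, timeouts excluded) and either
#' the momentary coordinate of that dot or the evidence accumulated up to it.
#' Computed for the decision-relevant x-coordinates this traces how strongly
#' each successive dot (and the running sum) drove choices; computed for the
#' y-coordinates it provides the decision-irrelevant control, expected near
#' zero throughout.
#'
#' @param outcomes a single outcome data.frame or a list of them (one per
#'   participant).
#' @param stimuli the shared `stimulus_set`.
#' @param coordinate `"x"` or `"y"`.
#' @param kind `"momentary"` (the dot's coordinate) or `"accumulated"`
#'   (running sum up to and including the dot).
#' @param dots dot indices to evaluate.
#' @return data.frame with columns `participant`, `dot`, `r`. Undefined
#'   correlations (zero variance) are returned as `NA` with a warning, never
#'   silently as 0.
#' @export
choice_evidence_correlation <- function(outcomes, stimuli,
                                        coordinate = c("x", "y"),
                                        kind = c("momentary", "accumulated"),
                                        dots = NULL) {
  coordinate <- match.arg(coordinate)
  kind <- match.arg(kind)
  if (is.data.frame(outcomes)) outcomes <- list(outcomes)
  val <- stim_matrix(stimuli, coordinate)
  if (kind == "accumulated") val <- t(apply(val, 1, cumsum))
  if (is.null(dots)) dots <- seq_len(ncol(val))
  res <- list()
  for (p in seq_along(outcomes)) {
    out <- outcomes[[p]]
    keep <- !out$timed_out
    if (sum(keep) < 3) stop("need >= 3 non-timeout trials per participant")
    ch <- out$choice[keep]
    vv <- val[out$trial_id[keep], , drop = FALSE]
    r <- vapply(dots, function(k) {
      if (stats::sd(ch) == 0 || stats::sd(vv[, k]) == 0) {
        warning("undefined correlation (zero variance) at participant ",
                p, ", dot ", k)
        return(NA_real_)
      }
      stats::cor(ch, vv[, k])
    }, numeric(1))
    res[[p]] <- data.frame(participant = p, dot = dots, r = r)
  }
  do.call(rbind, res)
}

#' One-way ANOVA of choice-evidence correlation across dots
#'
#' Tests whether the per-dot choice correlations differ across dot indices,
#' treating each participant x dot cell as one observation (between-cells
#' one-way ANOVA; with P participants and D dots the degrees of freedom are
#' D-1 and D*P - D).
#'
#' @param table correlation table from [choice_evidence_correlation()].
#' @param dots dot indices entering the ANOVA (default 1..14).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
dot_influence_anova <- function(table, dots = 1:14) {
  tab <- table[table$dot %in% dots, ]
  n_p <- length(unique(tab$participant))
  if (nrow(tab) != n_p * length(dots) || anyNA(tab$r))
    stop("correlation table incomplete for requested dots")
  fit <- stats::aov(r ~ factor(dot), data = tab)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       p = s[["Pr(>F)"]][1])
}

#' Paired t-test between two dots' choice correlations
#'
#' Two-sided paired t-test across participants comparing the choice
#' correlation at dot `i` with that at dot `j`.
#'
#' @param table correlation table from [choice_evidence_correlation()].
#' @param i,j dot indices to compare.
#' @return list with `t`, `df`, `p`.
#' @export
paired_dot_ttest <- function(table, i, j) {
  ri <- table$r[table$dot == i][order(table$participant[table$dot == i])]
  rj <- table$r[table$dot == j][order(table$participant[table$dot == j])]
  if (length(ri) != length(rj) || anyNA(ri) || anyNA(rj))
    stop("both dots must be present for all participants")
  if (length(ri) < 2) stop("need >= 2 participants")
  d <- ri - rj
  if (stats::sd(d) == 0) {
    # degenerate: identical columns give t = 0, a constant offset t = +/-Inf
    t0 <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t0, df = length(d) - 1, p = if (t0 == 0) 1 else 0))
  }
  tt <- stats::t.test(ri, rj, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
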