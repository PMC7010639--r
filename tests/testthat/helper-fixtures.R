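# shared small fixtures, built in code

# small stimulus set: 2*(6*3 + 6) = 48 trials
small_set <- function(seed = 42, n_long = 3, n_catch = 6) {
  build_stimulus_set(n_long = n_long, n_catch = n_catch, seed = seed)
}

small_outcomes <- function(stimuli, seed = 42) {
  simulate_behavior(stimuli, seed = seed)
}

# independent brute-force BH step-up, used as the FDR oracle
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  reject <- logical(m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# independent normal-equations OLS oracle
ols_oracle <- function(X, y) drop(solve(t(X) %*% X) %*% t(X) %*% y)

# brute-force row enumeration for the expanded design (independent of the
# vectorized implementation): walk every dot and test the three conditions
rows_oracle <- function(rt, t_from_onset, exclusion, max_dots = 25,
                        dur = 100) {
  n <- 0
  for (k in seq_len(max_dots)) {
    onset <- (k - 1) * dur
    s <- onset + t_from_onset
    if (onset < rt && s < rt && s < rt - exclusion) n <- n + 1
  }
  n
}
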