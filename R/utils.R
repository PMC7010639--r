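# shared internal helpers

# z-score with sample SD (n-1); with an intercept column this makes a
# single-regressor OLS coefficient equal the Pearson correlation exactly
zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot z-score a zero-variance vector")
  (v - mean(v)) / s
}

# scale to unit SD without centering (trial-time regressor contract)
unit_sd <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot scale a zero-variance vector")
  v / s
}

#' @noRd
is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x)

# tiny FNV-1a hash over a character scalar, for provenance tags only
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (h may exceed the integer range)
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit multiply by the FNV prime, split to stay exact in doubles
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # format as hex; h may exceed .Machine$integer.max, split into half-words
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
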