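one_trial <- function(rt, id = 1L) {
  data.frame(trial_id = id, rt_ms = rt, timed_out = FALSE)
}

test_that("row selection reproduces the worked example (rt 880, t 120)", {
  oc <- one_trial(880)
  # 9 dots shown before the response
  expect_equal(sum((seq_len(25) - 1) * 100 < 880), 9)
  # 8 candidate lagged samples before the response
  cand <- build_expanded_rows(oc, 120, design_config(exclusion_ms = 0))
  expect_equal(nrow(cand), 8)
  # 6 rows survive the 200 ms pre-response exclusion: dots 1-6, 120..620 ms
  rows <- build_expanded_rows(oc, 120)
  expect_equal(nrow(rows), 6)
  expect_equal(rows$dot_index, 1:6)
  expect_equal(rows$sample_time_ms, seq(120, 620, by = 100))
})

test_that("row counts agree with brute-force enumeration on an (rt, t) grid", {
  cfg <- design_config()
  for (rt in c(310, 500, 880, 1000, 1205, 2450)) {
    for (t in seq(0, 690, by = 30)) {
      got <- nrow(build_expanded_rows(one_trial(rt), t, cfg))
      expect_equal(got, rows_oracle(rt, t, 200),
                   info = sprintf("rt=%d t=%d", rt, t))
    }
  }
  expect_error(build_expanded_rows(one_trial(880), -10), ">= 0")
  expect_error(build_expanded_rows(one_trial(880), 125), "grid")
  # timed-out trials contribute nothing
  oc <- data.frame(trial_id = 1L, rt_ms = 2500, timed_out = TRUE)
  expect_equal(nrow(build_expanded_rows(oc, 120)), 0)
})

test_that("expanded design columns are z-scored and correctly valued", {
  ss <- small_set(seed = 81)
  out <- small_outcomes(ss, seed = 81)
  rows <- build_expanded_rows(out, 120)
  des <- build_expanded_design(ss, rows)
  X <- des$X
  for (cn in setdiff(colnames(X), "intercept")) {
    expect_equal(mean(X[, cn]), 0)
    expect_equal(sd(X[, cn]), 1)
  }
  expect_true(all(X[, "intercept"] == 1))
  # raw accumulated value at a dot-4 row equals the sum of the first 4 x
  desa <- build_expanded_design(ss, rows, design_config("accumulated"))
  r4 <- which(rows$dot_index == 4)[1]
  xm <- stim_matrix(ss, "x")
  raw <- vapply(seq_len(nrow(rows)), function(i)
    sum(xm[rows$trial_id[i], 1:rows$dot_index[i]]), numeric(1))
  expect_equal(desa$X[, "accum_x"], zscore(raw))
  expect_equal(raw[r4], sum(xm[rows$trial_id[r4], 1:4]))
  expect_false("accum_prev_x" %in% colnames(desa$X))
})

test_that("single-dot rows make accum_prev_x zero-variance and are caught", {
  ss <- small_set(seed = 82)
  rows <- data.frame(trial_id = 1:10, dot_index = 1, sample_time_ms = 120)
  expect_error(build_expanded_design(ss, rows), "accum_prev_x")
  cfg <- design_config(drop_zero_variance = TRUE)
  expect_message(des <- build_expanded_design(ss, rows, cfg), "accum_prev")
  expect_false("accum_prev_x" %in% colnames(des$X))
})

test_that("previous-sum regressor matches the Gram-Schmidt oracle", {
  ss <- small_set(seed = 83)
  out <- small_outcomes(ss, seed = 83)
  rows <- build_expanded_rows(out, 200)
  rows <- rows[rows$dot_index > 1, ]  # the identity concerns multi-dot rows
  xm <- stim_matrix(ss, "x")
  idx <- cbind(rows$trial_id, rows$dot_index)
  x_k <- xm[idx]
  full <- vapply(seq_len(nrow(rows)), function(i)
    sum(xm[rows$trial_id[i], 1:rows$dot_index[i]]), numeric(1))
  prev <- full - x_k
  # explicit orthogonalization oracle: residual of the full sum on x_k
  gs <- function(v, u) v - sum(v * u) / sum(u * u) * u
  res_full <- gs(full, x_k)
  # algebraic identity: residualizing the full sum equals residualizing the
  # previous sum (they differ by x_k, which projects out exactly)
  expect_equal(res_full, gs(prev, x_k), tolerance = 1e-12)
  # the previous sum matches the residual up to the target-mixture component
  # it shares with x_k (a genuine ~0.15 correlation when targets are pooled)
  expect_gt(cor(prev, res_full), 0.95)
})

test_that("standard design has 12 interest columns and unit-SD nuisances", {
  ss <- small_set(seed = 84)
  out <- small_outcomes(ss, seed = 84)
  des <- build_standard_design(ss, out)
  interest <- grep("^[xy]_", colnames(des$X), value = TRUE)
  expect_length(interest, 12)
  expect_equal(sd(des$X[, "trial_counter"]), 1)
  expect_equal(mean(des$X[, "response"]), 0)
  expect_true(all(des$X[, "intercept"] == 1))
  expect_false(any(out$trial_id[out$timed_out] %in% des$trial_id))
})

test_that("response design follows the choice/trial-time contract", {
  ss <- small_set(seed = 85)
  out <- small_outcomes(ss, seed = 85)
  des <- build_response_design(out)
  expect_equal(mean(des$X[, "choice"]), 0)
  expect_equal(sd(des$X[, "choice"]), 1)
  expect_equal(sd(des$X[, "trial_time"]), 1)
  expect_gt(mean(des$X[, "trial_time"]), 0)  # scaled, not centered
  expect_false(any(out$trial_id[out$timed_out] %in% des$trial_id))

  all_to <- out
  all_to$timed_out <- TRUE
  expect_error(build_response_design(all_to), "timed out")
})

test_that("signal z-scoring normalizes slices and commutes with permutation", {
  ss <- small_set(seed = 86)
  out <- small_outcomes(ss, seed = 86)
  tens <- simulate_session(ss, out, n_channels = 2, seed = 87)
  tz <- zscore_signal(tens)
  expect_equal(apply(tz$data, c(2, 3), mean),
               matrix(0, 2, length(tz$time_ms)), tolerance = 1e-12)
  expect_equal(apply(tz$data, c(2, 3), sd),
               matrix(1, 2, length(tz$time_ms)))
  # permute then z-score == z-score then permute
  perm <- permute_trials(tens, seed = 88)
  a <- zscore_signal(perm)$data
  b <- permute_trials(tz, seed = 88)$data
  expect_equal(a, b)
  # zero-variance slice is identified
  tens$data[, 1, 5] <- 7
  expect_error(zscore_signal(tens), "channel 1")
})

test_that("single z-scored regressor coefficient equals the Pearson r", {
  set.seed(89)
  for (i in 1:20) {
    n <- 50
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    X <- cbind(z = zscore(x), intercept = 1)
    b <- fit_ols(X, zscore(y))
    expect_equal(unname(b["z"]), cor(x, y), tolerance = 1e-10)
  }
})
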