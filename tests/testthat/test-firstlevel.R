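test_that("fit_ols agrees with the normal-equations oracle", {
  set.seed(91)
  for (i in 1:10) {
    X <- cbind(matrix(rnorm(50 * 4), 50, 4), 1)
    colnames(X) <- c(paste0("r", 1:4), "intercept")
    y <- rnorm(50)
    expect_equal(unname(fit_ols(X, y)), unname(ols_oracle(X, y)),
                 tolerance = 1e-8)
  }
})

test_that("fit_ols recovers an exact column and rejects rank deficiency", {
  set.seed(92)
  X <- cbind(a = rnorm(30), b = rnorm(30), intercept = 1)
  b <- fit_ols(X, X[, "a"])
  expect_equal(unname(b["a"]), 1)
  expect_lt(abs(b["b"]), 1e-12)

  Xr <- cbind(X, dup = X[, "a"])
  expect_error(fit_ols(Xr, rnorm(30)), "dup|a")
  expect_error(fit_ols(X[1:3, ], rnorm(3)), "more rows")
})

test_that("negating a regressor negates its coefficient exactly", {
  ss <- small_set(seed = 93)
  out <- small_outcomes(ss, seed = 93)
  rows <- build_expanded_rows(out, 150)
  des <- build_expanded_design(ss, rows)
  set.seed(94)
  y <- rnorm(nrow(des$X))
  b1 <- fit_ols(des$X, y)
  Xn <- des$X
  Xn[, "x"] <- -Xn[, "x"]
  b2 <- fit_ols(Xn, y)
  expect_equal(b1["x"], -b2["x"], tolerance = 1e-12)
})

test_that("trial permutation preserves content and is axis-consistent", {
  ss <- small_set(seed = 95)
  out <- small_outcomes(ss, seed = 95)
  tens <- simulate_session(ss, out, n_channels = 2, seed = 96)
  perm <- permute_trials(tens, seed = 97)
  # same multiset of trial slices, channels/times moved together
  key <- function(d) sort(d[, 1, 10])
  expect_equal(key(perm$data), key(tens$data))
  moved <- which(perm$data[, 1, 10] == tens$data[1, 1, 10])[1]
  expect_equal(perm$data[moved, , ], tens$data[1, , ])
})

test_that("permuted data flattens the expanded coefficient time course", {
  ss <- small_set(seed = 98)
  out <- small_outcomes(ss, seed = 98)
  ef <- effect_spec("x", 120, weights = c(1, 0), amplitude = 1)
  tens <- simulate_session(ss, out, effects = list(ef), n_channels = 2,
                           seed = 99)
  fl <- run_expanded(tens, ss, out, times = c(120, 400))
  flp <- run_expanded(permute_trials(tens, seed = 100), ss, out,
                      times = c(120, 400))
  expect_gt(abs(fl$beta["x", 1, 1]), 0.5)
  expect_lt(abs(flp$beta["x", 1, 1]), 0.2)
})

test_that("null permutation coefficients are centered on zero", {
  # empirical null of the evidence coefficient over repeated permutations
  ss <- small_set(seed = 101)
  out <- small_outcomes(ss, seed = 101)
  tens <- simulate_session(ss, out, n_channels = 1, seed = 102)
  bs <- vapply(1:50, function(i) {
    flp <- run_expanded(permute_trials(tens, seed = 200 + i), ss, out,
                        times = 120)
    flp$beta["x", 1, 1]
  }, numeric(1))
  n <- sum(!out$timed_out)
  expect_lt(abs(mean(bs)), 3 * sd(bs) / sqrt(length(bs)))
})

test_that("response-aligned grid and window aggregation are consistent", {
  ss <- small_set(seed = 103)
  out <- small_outcomes(ss, seed = 103)
  tens <- simulate_session(ss, out, n_channels = 2, seed = 104)
  des <- build_response_design(out)
  fl <- run_pertrial(tens, des, times = c(-120, 0, 30), align = "response")
  expect_equal(dim(fl$beta), c(3, 2, 3))
  # one-sample window equals the per-time fit at that sample
  wa <- run_window_aggregate(tens, des, c(30, 30))
  expect_equal(unname(wa$beta["choice", ]), unname(fl$beta["choice", , 3]))
  expect_error(run_window_aggregate(tens, des, c(100, -100)), "start <= end")
})

test_that("expanded variants agree where the evidence regressors coincide", {
  # restricted to dot-1 rows the running sum equals the current x, so the
  # two variants' evidence coefficients match (nuisance set reduced to the
  # shared columns to keep both designs full rank)
  ss <- small_set(seed = 105)
  out <- small_outcomes(ss, seed = 105)
  rows <- build_expanded_rows(out, 120)
  rows <- rows[rows$dot_index == 1, ]
  cfg_m <- design_config("momentary", nuisance = FALSE)
  cfg_a <- design_config("accumulated", nuisance = FALSE)
  dm <- build_expanded_design(ss, rows, cfg_m)
  da <- build_expanded_design(ss, rows, cfg_a)
  expect_equal(unname(dm$X[, "x"]), unname(da$X[, "accum_x"]))
})
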