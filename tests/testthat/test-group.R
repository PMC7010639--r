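beta_arrays <- function(n, d, f) lapply(seq_len(n), function(i) {
  a <- array(f(prod(d), i), dim = d,
             dimnames = list(paste0("r", seq_len(d[1])), NULL, NULL))
  a
})

test_that("second-level t-tests have the across-participant dof and p-values", {
  set.seed(111)
  betas <- beta_arrays(34, c(1, 3, 4), function(m, i) rnorm(m, 0.2, 0.5))
  grp <- second_level(betas)
  expect_equal(grp$n_participants, 34)
  # p follows the t distribution with dof 33
  expect_equal(grp$p, 2 * pt(-abs(grp$t), df = 33))
  # matches t.test cell-by-cell
  v <- sapply(betas, function(b) b[1, 2, 3])
  tt <- t.test(v)
  expect_equal(unname(grp$t[1, 2, 3]), unname(tt$statistic))
  expect_equal(unname(grp$p[1, 2, 3]), tt$p.value)
})

test_that("degenerate zero-variance cells are handled without overflow", {
  betas <- beta_arrays(5, c(1, 2, 1), function(m, i) c(0.7, 0))
  grp <- second_level(betas)
  expect_true(is.infinite(grp$t[1, 1, 1]))
  expect_equal(unname(grp$p[1, 1, 1]), 0)
  expect_equal(unname(grp$t[1, 2, 1]), 0)
  expect_equal(unname(grp$p[1, 2, 1]), 1)
  expect_error(second_level(betas[1]), ">= 2")
  bad <- c(betas[1:4], beta_arrays(1, c(1, 3, 1), function(m, i) 0))
  expect_error(second_level(bad), "misaligned")
})

test_that("BH correction matches the independent step-up oracle", {
  set.seed(112)
  for (i in 1:50) {
    p <- runif(sample(50:300, 1))^sample(1:3, 1)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_correct(p, alpha), bh_oracle(p, alpha))
  }
  expect_equal(sum(fdr_correct(rep(1, 100), 0.05)), 0)
  expect_error(fdr_correct(c(0.5, 2)), "0, 1")
})

test_that("the default area-level grid corrects across 25,340 hypotheses", {
  n_cells <- length(seq(0, 690, by = 10)) * nrow(parcellation_labels())
  expect_equal(n_cells, 25340)
  set.seed(113)
  p <- array(runif(n_cells), dim = c(1, 362, 70))
  mask <- fdr_correct(p, 0.05)
  expect_identical(dim(mask), dim(p))
  expect_identical(as.vector(mask), bh_oracle(as.vector(p), 0.05))
})

test_that("grand-average magnitude rectifies after averaging", {
  d <- c(1, 2, 3)
  b1 <- array(c(1, -1, 2, -2, 3, -3), dim = d,
              dimnames = list("r1", NULL, NULL))
  r1 <- list(beta = b1, times = c(0, 10, 20))
  ga <- grand_average_magnitude(list(r1), "r1")
  expect_equal(unname(ga$magnitude), c(1, 2, 3))
  # rectify-after-average <= average-of-rectified, strict when signs mix
  b2 <- -b1
  r2 <- list(beta = b2, times = c(0, 10, 20))
  ga2 <- grand_average_magnitude(list(r1, r2), "r1")
  avg_of_rect <- colMeans((abs(b1[1, , ]) + abs(b2[1, , ])) / 2)
  expect_true(all(ga2$magnitude <= avg_of_rect + 1e-12))
  expect_equal(unname(ga2$magnitude), c(0, 0, 0))  # opposite signs cancel
})

test_that("significant windows are contiguous intervals with ranked locations", {
  times <- seq(0, 690, by = 10)
  n_loc <- 5
  mask <- matrix(FALSE, n_loc, length(times),
                 dimnames = list(paste0("L", 1:5), NULL))
  tmat <- matrix(0, n_loc, length(times), dimnames = dimnames(mask))
  expect_length(significant_windows(mask, tmat, times), 0)
  # two disjoint blobs: location 2 around 120 ms, locations 3+4 at 400-450
  mask[2, times >= 110 & times <= 130] <- TRUE
  tmat[2, times >= 110 & times <= 130] <- 4
  mask[3, times >= 400 & times <= 450] <- TRUE
  tmat[3, times >= 400 & times <= 450] <- 6
  mask[4, times == 420] <- TRUE
  tmat[4, times >= 400 & times <= 450] <- 3
  win <- significant_windows(mask, tmat, times)
  expect_length(win, 2)
  expect_equal(win[[1]]$start_ms, 110)
  expect_equal(win[[1]]$end_ms, 130)
  expect_equal(win[[2]]$start_ms, 400)
  expect_equal(win[[2]]$end_ms, 450)
  # ranking by time-averaged |t| within the window
  expect_equal(win[[2]]$locations$location, c("L3", "L4"))
  expect_gt(win[[2]]$locations$mean_abs_t[1],
            win[[2]]$locations$mean_abs_t[2])
})

test_that("second-level false-positive rate is near nominal under the null", {
  set.seed(114)
  fp <- replicate(80, {
    betas <- beta_arrays(10, c(1, 4, 5), function(m, i) rnorm(m))
    grp <- second_level(betas)
    mean(grp$p < 0.05)
  })
  expect_lt(abs(mean(fp) - 0.05), 3 * sd(fp) / sqrt(length(fp)) + 0.01)
})
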