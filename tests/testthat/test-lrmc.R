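test_that("svt shrinks singular values and matches the eigen-based oracle", {
  # diagonal case: svt(diag(3,1), 1) = diag(2,0)
  expect_equal(svt(diag(c(3, 1)), 1), diag(c(2, 0)), tolerance = 1e-12)
  # zero threshold is the identity (up to rank cap)
  set.seed(4)
  M <- matrix(rnorm(20), 4, 5)
  expect_equal(svt(M, 0), M, tolerance = 1e-10)
  # random matrices against an independent full decomposition
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:50, 1); m <- sample(2:50, 1)
    A <- matrix(rnorm(n * m), n, m)
    thr <- runif(1, 0, 2)
    expect_lt(max(abs(svt(A, thr) - svt_oracle(A, thr))), 1e-10)
  }
  expect_error(svt(matrix(c(1, NA), 1), 1), "non-finite")
})

test_that("svt is nonexpansive in the Frobenius norm", {
  for (seed in 1:10) {
    set.seed(seed)
    A <- matrix(rnorm(30), 5, 6)
    B <- matrix(rnorm(30), 5, 6)
    t <- runif(1, 0, 3)
    expect_lte(norm(svt(A, t) - svt(B, t), "F"), norm(A - B, "F") + 1e-12)
  }
})

test_that("fpca_complete reproduces fully observed and zero matrices", {
  set.seed(2)
  M <- matrix(rnorm(60), 6, 10)
  res <- fpca_complete(M, cfg = fpca_config(mu_final_ratio = 1e-6))
  expect_lt(max(abs(res$completed - M)), 1e-3)

  Z <- matrix(0, 5, 5)
  mask <- matrix(runif(25) < 0.5, 5, 5)
  mask[1, 1] <- TRUE
  expect_equal(fpca_complete(Z, mask)$completed, Z)

  expect_error(fpca_complete(M, matrix(FALSE, 6, 10)), "no observed")
})

test_that("fpca_complete recovers an exact rank-1 matrix from half the entries", {
  sim <- simulate_lowrank(20, 30, 1, seed = 5)
  set.seed(6)
  mask <- matrix(runif(600) < 0.5, 20, 30)
  # small problems leave a visible objective plateau; ask for a tight fit
  res <- fpca_complete(sim$M, mask, fpca_config(rel_tol = 1e-8))
  expect_lt(rel_frob(res$completed, sim$M), 1e-3)
  expect_true(res$converged)
})

test_that("fpca objective is non-increasing within each continuation stage", {
  sim <- simulate_lowrank(15, 20, 2, seed = 8)
  set.seed(9)
  mask <- matrix(runif(300) < 0.6, 15, 20)
  res <- fpca_complete(sim$M, mask)
  for (s in unique(res$objective_stage)) {
    h <- res$objective_history[res$objective_stage == s]
    if (length(h) > 1) {
      expect_true(all(diff(h) <= 1e-10 * pmax(1, abs(h[-length(h)]))))
    }
  }
})

test_that("window geometry validates and covers all columns", {
  expect_error(window_spec(10, 10), "overlap < width")
  expect_error(window_spec(10, -1), "overlap < width")
  wins <- rankimpute:::window_starts(25, 10, 3)
  expect_equal(sort(unique(unlist(wins))), 1:25)
  expect_identical(rankimpute:::window_starts(5, 10, 3), list(1:5))
})

test_that("single full-width window equals fpca_complete exactly", {
  sim <- simulate_lowrank(12, 18, 2, seed = 10)
  set.seed(11)
  mask <- matrix(runif(12 * 18) < 0.7, 12, 18)
  full <- fpca_complete(sim$M, mask)
  win <- lrmc_s_complete(sim$M, mask, window = window_spec(width = 18, overlap = 0))
  expect_identical(win$completed, full$completed)
  expect_length(win$per_window_ranks, 1L)
})

test_that("windows aligned to rank-1 blocks recover each block", {
  s1 <- simulate_lowrank(15, 10, 1, seed = 12)
  s2 <- simulate_lowrank(15, 10, 1, seed = 13)
  M <- cbind(s1$M, s2$M)
  set.seed(14)
  mask <- matrix(runif(300) < 0.6, 15, 20)
  # sparsely observed rows make the fixed-point slow; allow it to converge
  res <- lrmc_s_complete(M, mask,
                         cfg = fpca_config(rel_tol = 1e-10, max_inner = 5000,
                                           mu_final_ratio = 1e-6),
                         window = window_spec(width = 10, overlap = 0))
  expect_lt(rel_frob(res$completed[, 1:10], s1$M), 1e-3)
  expect_lt(rel_frob(res$completed[, 11:20], s2$M), 1e-3)
  expect_length(res$per_window_ranks, 2L)
})

test_that("average_overlap stitches overlap columns as the mean of window estimates", {
  set.seed(15)
  M <- matrix(rnorm(8 * 12), 8, 12)
  mask <- matrix(TRUE, 8, 12)
  cfg <- fpca_config(max_inner = 5, max_outer = 3)
  spec <- window_spec(width = 8, overlap = 4, stitch = "average_overlap")
  res <- lrmc_s_complete(M, mask, cfg = cfg, window = spec)
  left <- fpca_complete(M[, 1:8], mask[, 1:8], cfg)$completed
  right <- fpca_complete(M[, 5:12], mask[, 5:12], cfg)$completed
  expect_equal(res$completed[, 5:8], (left[, 5:8] + right[, 1:4]) / 2,
               tolerance = 1e-12)
  # left_priority keeps the earlier window's estimate instead
  res_l <- lrmc_s_complete(M, mask, cfg = cfg,
                           window = window_spec(8, 4, "left_priority"))
  expect_equal(res_l$completed[, 1:8], left, tolerance = 1e-12)
})

test_that("completion succeeds at 50% sampling and fails at 2% (phase behavior)", {
  sim <- simulate_lowrank(200, 300, 2, seed = 11)
  set.seed(12)
  mask_ok <- matrix(runif(200 * 300) < 0.5, 200, 300)
  expect_lt(rel_frob(fpca_complete(sim$M, mask_ok)$completed, sim$M), 1e-3)
  set.seed(13)
  mask_low <- matrix(runif(200 * 300) < 0.02, 200, 300)
  expect_gt(rel_frob(fpca_complete(sim$M, mask_low)$completed, sim$M), 0.1)
})
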