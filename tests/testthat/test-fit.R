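small_sim <- function(seed = 1, N = 200, M = 30, K = 3, phi = 0.15) {
  simulate_spatial_counts(N, M, K, phi_true = phi, mean_depth = 80, seed = seed)
}

test_that("warm start returns the best of its candidate runs", {
  sim <- small_sim(2, N = 60, M = 12, K = 2)
  ws <- warm_start(sim$V, K = 2, n_init = 3, n_iter = 40, seed = 10)
  # recompute each candidate independently and compare
  singles <- vapply(1:3, function(r) {
    suppressWarnings(
      warm_start(sim$V, K = 2, n_init = 1, n_iter = 40, seed = 10 + r - 1))$gkl
  }, numeric(1))
  expect_equal(ws$gkl_all, singles, tolerance = 1e-12)
  expect_equal(ws$gkl, min(singles))
  expect_equal(ws$init, which.min(singles))
  expect_equal(unname(rowSums(ws$H)), rep(1, 2), tolerance = 1e-10)
  expect_warning(warm_start(sim$V, K = 2, n_init = 2, n_iter = 5, seed = 1),
                 "initializations")
  expect_error(warm_start(sim$V, K = 100, seed = 1), "min")
})

test_that("smoothing update equals the hand-computed weighted averages", {
  # the collinear 0, 1, 2 kernel at phi = 1
  X <- cbind(c(0, 1, 2))
  k <- gaussian_kernel(X, 1, cutoff = Inf)
  W <- matrix(c(1, 0, 2, 3, 1, 0), 3, 2)
  out <- smoothing_update(W, list(k), batch_partition(rep(1L, 3)))
  S <- matrix(c(1, exp(-1), exp(-4),
                exp(-1), 1, exp(-1),
                exp(-4), exp(-1), 1), 3, 3, byrow = TRUE)
  expect_equal(out, smoothing_oracle(S, W), tolerance = 1e-12)

  # identity kernel leaves W unchanged
  idk <- list(S_rn = diag(3))
  expect_identical(smoothing_update(W, idk, batch_partition(rep(1L, 3))), W)
  expect_error(smoothing_update(W, list(k), batch_partition(c(1L, 1L, 2L, 2L))),
               "cell count")
})

test_that("per-batch smoothing touches only same-batch rows", {
  sim <- small_sim(4, N = 80)
  p <- groupondist(sim$X, 40, seed = 2)
  kernels <- lapply(1:p$n_batches, function(b)
    gaussian_kernel(sim$X[p$assignment == b, , drop = FALSE], 0.2))
  W <- matrix(runif(80 * 3), 80, 3)
  out <- smoothing_update(W, kernels, p)
  for (b in 1:p$n_batches) {
    idx <- which(p$assignment == b)
    expect_equal(out[idx, ],
                 as.matrix(kernels[[b]]$S_rn %*% W[idx, ]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_true(all(out >= 0))
})

test_that("phi = 0 reduces the fit to plain Poisson NMF with a monotone trace", {
  sim <- small_sim(3, N = 100, M = 20)
  f0 <- fit_nnmf(sim$V, sim$X, K = 3, phi = 0, max_iter = 60, seed = 5)
  fp <- fit_nnmf(sim$V, K = 3, max_iter = 60, seed = 5)
  expect_identical(f0$W, fp$W)
  expect_identical(f0$H, fp$H)
  expect_identical(f0$gkl_trace, fp$gkl_trace)
  expect_true(all(diff(fp$gkl_trace) <= 1e-8))
  expect_equal(unname(rowSums(fp$H)), rep(1, 3), tolerance = 1e-10)
  expect_true(all(fp$W >= 0) && all(fp$H >= 0))
})

test_that("fits are deterministic and batching with one batch is a no-op", {
  sim <- small_sim(6, N = 120, M = 20)
  a <- fit_nnmf(sim$V, sim$X, K = 2, phi = 0.2, max_iter = 40, seed = 9)
  b <- fit_nnmf(sim$V, sim$X, K = 2, phi = 0.2, max_iter = 40, seed = 9)
  expect_identical(a$W, b$W)
  expect_identical(a$H, b$H)
  expect_identical(a$gkl_trace, b$gkl_trace)

  # single slice label must match the unbatched fit bit for bit
  s <- fit_nnmf(sim$V, sim$X, K = 2, phi = 0.2, max_iter = 40, seed = 9,
                slices = rep("slice1", 120))
  expect_identical(a$W, s$W)
  expect_identical(a$H, s$H)
  expect_identical(a$gkl_trace, s$gkl_trace)
})

test_that("non-convergence is reported in metadata, not as an error", {
  sim <- small_sim(8, N = 60, M = 10, K = 2)
  f <- fit_nnmf(sim$V, sim$X, K = 2, phi = 0.2, max_iter = 3, seed = 1)
  expect_false(f$converged)
  expect_equal(f$n_iter, 3L)
  expect_length(f$gkl_trace, 3L)
  expect_true(all(is.finite(f$gkl_trace)))
})

test_that("AIC follows 2*GKL + 2*(NK + KM)", {
  # perfect rank-1 fit of a 2x3 matrix: the divergence term vanishes
  W <- matrix(c(1, 2), 2, 1)
  H <- matrix(c(0.2, 0.3, 0.5), 1, 3)
  expect_equal(nnmf_aic(W %*% H, W, H), 2 * (2 + 3), tolerance = 1e-10)

  inst <- random_instance(5, 4, 2, 17)
  expect_equal(nnmf_aic(inst$V, inst$W, inst$H),
               aic_oracle(inst$V, inst$W, inst$H), tolerance = 1e-10)

  # the parameter-count part of the AIC difference between ranks is 2(N + M)
  inst3 <- random_instance(5, 4, 3, 18)
  d_gkl <- gkl_divergence(inst$V, inst3$W, inst3$H) -
    gkl_divergence(inst$V, inst$W, inst$H)
  expect_equal(nnmf_aic(inst$V, inst3$W, inst3$H) - nnmf_aic(inst$V, inst$W, inst$H),
               2 * d_gkl + 2 * (5 + 4), tolerance = 1e-10)
})

test_that("select_k returns a consistent AIC curve and breaks ties to smaller K", {
  sim <- small_sim(12, N = 150, M = 25, K = 3)
  sc <- select_k(sim$V, sim$X, k_grid = c(2, 3, 4), phi = 0.15,
                 max_iter = 60, tol = 1e-5, seed = 4)
  expect_equal(sc$n_prm_values, 150 * c(2, 3, 4) + c(2, 3, 4) * 25)
  expect_true(all(diff(sc$n_prm_values) > 0))
  # stored AIC agrees with recomputation on the stored fits
  recomputed <- vapply(sc$fits, function(f) nnmf_aic(sim$V, f), numeric(1))
  expect_equal(sc$aic_values, recomputed, tolerance = 1e-12)
  expect_equal(sc$best_k, sc$k_grid[which.min(sc$aic_values)])

  # a one-element grid is its own argmin
  sc1 <- select_k(sim$V, sim$X, k_grid = 3, phi = 0.15, max_iter = 30, seed = 4)
  expect_equal(sc1$best_k, 3L)
})

test_that("smoothing raises the spatial autocorrelation of the weights", {
  skip_if_not_installed("ape")
  sim <- small_sim(21, N = 250, M = 40, K = 3, phi = 0.15)
  fn <- fit_nnmf(sim$V, sim$X, K = 3, phi = 0.15, max_iter = 120, seed = 2)
  fp <- fit_nnmf(sim$V, K = 3, max_iter = 120, seed = 2)
  Wt <- as.matrix(gaussian_kernel(sim$X, 0.15)$S)
  diag(Wt) <- 0
  moran <- function(W) mean(vapply(seq_len(ncol(W)), function(j)
    ape::Moran.I(W[, j], Wt)$observed, numeric(1)))
  expect_gt(moran(fn$W), moran(fp$W))
})
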