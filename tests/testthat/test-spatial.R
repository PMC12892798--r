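test_that("gaussian kernel matches hand evaluation of the formula", {
  # three collinear points at 0, 1, 2 with phi = 1
  k <- gaussian_kernel(cbind(c(0, 1, 2)), phi = 1, cutoff = Inf)
  S <- as.matrix(k$S)
  expected <- matrix(c(1, exp(-1), exp(-4),
                       exp(-1), 1, exp(-1),
                       exp(-4), exp(-1), 1), 3, 3, byrow = TRUE)
  expect_equal(S, expected, tolerance = 1e-12, ignore_attr = TRUE)

  # coincident points and points at distance exactly phi
  k2 <- gaussian_kernel(rbind(c(0, 0), c(0, 0), c(3, 4)), phi = 5)
  S2 <- as.matrix(k2$S)
  expect_equal(S2[1, 2], 1)
  expect_equal(S2[1, 3], exp(-1), tolerance = 1e-12)
  expect_true(isSymmetric(unname(S2)))
  expect_identical(unname(diag(S2)), rep(1, 3))
  # row-normalized form is row-stochastic
  expect_equal(unname(Matrix::rowSums(k2$S_rn)), rep(1, 3), tolerance = 1e-12)
})

test_that("kernel decays with distance and grows with phi", {
  d <- seq(0.5, 3, by = 0.5)
  vals <- vapply(d, function(x)
    as.matrix(gaussian_kernel(cbind(c(0, x)), 1, cutoff = Inf)$S)[1, 2],
    numeric(1))
  expect_true(all(diff(vals) < 0))
  phis <- c(0.5, 1, 2, 4)
  vals2 <- vapply(phis, function(p)
    as.matrix(gaussian_kernel(cbind(c(0, 1)), p, cutoff = Inf)$S)[1, 2],
    numeric(1))
  expect_true(all(diff(vals2) > 0))
  expect_error(gaussian_kernel(cbind(0), phi = 0), "positive")
  expect_error(gaussian_kernel(cbind(c(0, NA)), phi = 1), "finite")
})

test_that("length-scale search reproduces the brute-force error curve", {
  sim <- simulate_spatial_counts(60, 10, 2, phi_true = 0.2, mean_depth = 50,
                                 seed = 5)
  grid <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  for (mode in c("squared", "literal")) {
    sel <- suppressWarnings(
      select_length_scale(sim$V, sim$X, grid, mode = mode, cutoff = Inf))
    oracle <- vapply(grid, function(p)
      length_scale_error_oracle(sim$V, sim$X, p, mode), numeric(1))
    expect_equal(sel$errors, oracle, tolerance = 1e-8)
    expect_equal(sel$phi, grid[order(oracle, grid)[1]])
  }
})

test_that("length-scale search edge cases: single candidate, constant field, ties", {
  sim <- simulate_spatial_counts(30, 5, 2, phi_true = 0.2, seed = 9)
  expect_equal(select_length_scale(sim$V, sim$X, 0.3)$phi, 0.3)

  # a constant expression field is perfectly predicted by any neighborhood
  # average; ties break toward the smallest phi
  Vc <- matrix(4, 20, 3)
  Xc <- matrix(runif(40), 20, 2)
  sel <- select_length_scale(Vc, Xc, c(0.5, 0.2, 1), cutoff = Inf)
  expect_equal(sel$errors, rep(0, 3), tolerance = 1e-12)
  expect_equal(sel$phi, 0.2)

  # isolated cells at a tiny phi are predicted as zero, with a warning
  Xi <- rbind(c(0, 0), c(0, 1e-4), c(5, 5))
  Vi <- matrix(1:6, 3, 2)
  expect_warning(select_length_scale(Vi, Xi, 1e-3), "no neighbor")
})

test_that("groupondist builds exact partitions with all-but-last batches full", {
  # hand-traceable case: 5 collinear points, batch size 2
  X <- cbind(c(0, 1, 2, 3, 4))
  p <- groupondist(X, batch_size = 2, seed = 1)
  expect_setequal(p$assignment, 1:3)
  expect_equal(sort(p$sizes, decreasing = TRUE), c(2, 2, 1))
  expect_equal(p$sizes, c(2L, 2L, 1L)) # remainder forms the last batch

  # N <= batch_size: a single batch
  p1 <- groupondist(matrix(runif(10), 5, 2), batch_size = 10, seed = 3)
  expect_equal(p1$n_batches, 1L)
  expect_equal(p1$sizes, 5L)

  # partition property and determinism at larger N
  for (seed in 1:3) {
    X2 <- matrix(runif(2 * 997), 997, 2)
    pa <- groupondist(X2, 100, seed = seed)
    pb <- groupondist(X2, 100, seed = seed)
    expect_identical(pa$assignment, pb$assignment)
    expect_equal(sum(pa$sizes), 997L)
    expect_true(all(pa$sizes[-pa$n_batches] == 100L))
    expect_true(all(tabulate(pa$assignment) >= 1L))
  }
})

test_that("slice batches follow the labels and preserve order", {
  p <- slice_batches(c("A", "A", "B", "B"))
  expect_equal(p$assignment, c(1L, 1L, 2L, 2L))
  expect_equal(p$sizes, c(2L, 2L))
  expect_error(slice_batches(c("A", NA)), "slice label")
  # batches numbered by first appearance
  p2 <- slice_batches(c("z", "a", "z", "a"))
  expect_equal(p2$assignment, c(1L, 2L, 1L, 2L))
})

test_that("kernel entry counts reproduce the exact batching bookkeeping", {
  expect_identical(kernel_entry_count(50627), 50627^2)
  expect_identical(kernel_entry_count(c(24594, 26033)), 24594^2 + 26033^2)
  expect_identical(kernel_entry_count(1), 1)
  # splitting any batch strictly reduces the stored entries
  for (a in c(1, 10, 500)) for (b in c(1, 7, 123)) {
    expect_lt(kernel_entry_count(c(a, b)), kernel_entry_count(a + b))
  }
})

test_that("smoothing a constant weight field is the identity", {
  X <- matrix(runif(60), 30, 2)
  k <- gaussian_kernel(X, 0.3, cutoff = Inf)
  W <- matrix(rep(c(2, 5, 1), each = 30), 30, 3)
  p <- batch_partition(rep(1L, 30))
  expect_equal(smoothing_update(W, list(k), p), W, tolerance = 1e-12)
})
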