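# The full NNMF algorithm: warm start, the H / W / smoothing iteration,
# convergence control, AIC and rank selection.

#' Warm start from the best of several plain Poisson-NMF runs
#'
#' The multiplicative updates only reach a local optimum, so the fit is
#' initialized by running plain Poisson NMF (no smoothing) for a modest
#' number of iterations from several independent uniform(0, 1) random
#' starts and keeping the factorization with the smallest GKL divergence.
#' At least three initializations are recommended; fewer triggers a
#' warning. Fully deterministic given `seed` (run r uses `seed + r - 1`).
#'
#' @param V count matrix (N x M), dense or sparse.
#' @param K number of signatures; must not exceed `min(N, M)`.
#' @param n_init number of random starts (default 3).
#' @param n_iter plain-NMF iterations per start (default 100; 50-100 is the
#'   intended range).
#' @param seed integer seed.
#' @return A list with the winning `W`, row-stochastic `H`, its `gkl`, the
#'   winning start index `init`, and `gkl_all` across starts.
#' @export
warm_start <- function(V, K, n_init = 3L, n_iter = 100L, seed = 1L) {
  assert_counts(V)
  N <- nrow(V); M <- ncol(V)
  if (K < 1L || K > min(N, M)) stop("K must be in 1..min(N, M)")
  if (n_init < 1L) stop("n_init must be >= 1")
  if (n_init < 3L) warning("fewer than 3 initializations; local optima are more likely")
  best <- NULL
  gkl_all <- numeric(n_init)
  for (r in seq_len(n_init)) {
    withr::with_seed(as.integer(seed) + r - 1L, {
      W <- matrix(stats::runif(N * K), N, K)
      H <- row_normalize(matrix(stats::runif(K * M), K, M))
    })
    for (it in seq_len(n_iter)) {
      H <- update_h(V, W, H)
      W <- update_w(V, W, H)
    }
    gkl_all[r] <- gkl_divergence(V, W, H)
    if (is.null(best) || gkl_all[r] < best$gkl)
      best <- list(W = W, H = H, gkl = gkl_all[r], init = r)
  }
  best$gkl_all <- gkl_all
  best
}

#' Neighborhood smoothing of the weight matrix
#'
#' Applies \eqn{W^b \leftarrow \mathrm{rnorm}(S^b)\, W^b} batch by batch:
#' every row of the result is a convex combination of same-batch rows of
#' the input, so nonnegativity is preserved and a constant weight field is
#' left unchanged.
#'
#' @param W weight matrix (N x K).
#' @param kernels list with one [gaussian_kernel()] (or a bare
#'   row-stochastic matrix) per batch, in batch order.
#' @param batches a [batch_partition()] covering the rows of W.
#' @return Smoothed weight matrix of the same shape.
#' @export
smoothing_update <- function(W, kernels, batches) {
  if (!inherits(batches, "batch_partition")) stop("batches must be a batch_partition")
  a <- batches$assignment
  if (length(a) != nrow(W)) stop("batch assignment and W disagree on cell count")
  if (length(kernels) != batches$n_batches)
    stop("need exactly one kernel per batch")
  for (b in seq_along(kernels)) {
    idx <- which(a == b)
    S_rn <- if (inherits(kernels[[b]], "smoothing_kernel")) kernels[[b]]$S_rn else kernels[[b]]
    if (nrow(S_rn) != length(idx))
      stop(sprintf("kernel %d has %d rows but batch %d has %d cells",
                   b, nrow(S_rn), b, length(idx)))
    W[idx, ] <- as.matrix(S_rn %*% W[idx, , drop = FALSE])
  }
  W
}

#' Fit neighborhood NMF
#'
#' Decomposes a nonnegative count matrix V (cells x genes) as
#' \eqn{V \approx W H} with K spatially smooth signatures by iterating,
#' until convergence,
#' \enumerate{
#'   \item \eqn{H \leftarrow \mathrm{rnorm}(H \otimes (W^\top V / WH))},
#'   \item \eqn{W \leftarrow W \otimes ((V / WH) H^\top)},
#'   \item \eqn{W^b \leftarrow \mathrm{rnorm}(S^b_\phi)\, W^b} for each
#'     batch b,
#' }
#' starting from a [warm_start()]. Steps 1-2 are the Poisson-NMF
#' multiplicative updates (GKL non-increasing); step 3 averages each cell's
#' weights over its spatial neighborhood so nearby cells share correlated
#' signature activity. With `phi = 0` (or no coordinates) the smoothing
#' step is skipped and the fit is plain Poisson NMF.
#'
#' The GKL divergence is recorded after the smoothing step of every
#' iteration; smoothing can transiently raise it, so the trace is only
#' guaranteed monotone when smoothing is off. Convergence is declared when
#' the relative change `|gkl[t-1] - gkl[t]| / max(gkl[t], 1)` drops below
#' `tol`; a fit that exhausts `max_iter` is returned with
#' `converged = FALSE` rather than raising an error.
#'
#' @inheritParams warm_start
#' @param X coordinate matrix (N x d), or `NULL` for plain NMF.
#' @param phi smoothing length scale; `NULL` (default) estimates it with
#'   [select_length_scale()] over `phi_grid`; `0` disables smoothing.
#' @param phi_grid candidate grid for the length-scale search; `NULL` uses
#'   a data-driven log-spaced grid.
#' @param batches optional [batch_partition()]; default is a single batch,
#'   or one batch per slice when `slices` is given.
#' @param slices optional per-cell slice labels (see [slice_batches()]).
#' @param max_iter iteration cap (default 1000).
#' @param tol relative GKL convergence tolerance (default 1e-6).
#' @param smooth_every apply the smoothing step every `smooth_every`
#'   iterations (default 1, i.e. every iteration).
#' @param cutoff kernel truncation radius in units of phi.
#' @return An object of class `nnmf_fit`: `W` (N x K), `H` (K x M,
#'   row-stochastic), `K`, `phi`, `gkl_trace`, `n_iter`, `converged`,
#'   `seed`, `batches`, `dead_signatures` (indices of all-zero W columns)
#'   and warm-start metadata.
#' @export
fit_nnmf <- function(V, X = NULL, K, phi = NULL, phi_grid = NULL,
                     batches = NULL, slices = NULL,
                     max_iter = 1000L, tol = 1e-6, seed = 1L,
                     n_init = 3L, n_warm_iter = 100L,
                     smooth_every = 1L, cutoff = 3) {
  assert_counts(V)
  N <- nrow(V)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != N) stop("coordinates and counts disagree on cell count")
  }
  if (is.null(batches)) {
    batches <- if (!is.null(slices)) slice_batches(slices)
               else batch_partition(rep(1L, N))
  }
  if (length(batches$assignment) != N)
    stop("batch assignment and counts disagree on cell count")

  if (is.null(phi)) {
    if (is.null(X)) {
      phi <- 0
    } else {
      if (is.null(phi_grid)) phi_grid <- default_phi_grid(X)
      phi <- select_length_scale(V, X, phi_grid)$phi
    }
  }
  smooth <- !is.null(X) && phi > 0
  kernels <- if (smooth) {
    lapply(seq_len(batches$n_batches), function(b)
      gaussian_kernel(X[batches$assignment == b, , drop = FALSE], phi,
                      cutoff = cutoff))
  }

  ws <- warm_start(V, K, n_init = n_init, n_iter = n_warm_iter, seed = seed)
  W <- ws$W
  H <- row_normalize(ws$H)

  gkl_trace <- numeric(0)
  converged <- FALSE
  gkl_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- update_h(V, W, H)
    W <- update_w(V, W, H)
    if (smooth && it %% smooth_every == 0L)
      W <- smoothing_update(W, kernels, batches)
    gkl <- gkl_divergence(V, W, H)
    gkl_trace[it] <- gkl
    if (is.finite(gkl_prev) && abs(gkl_prev - gkl) / max(gkl, 1) < tol) {
      converged <- TRUE
      break
    }
    gkl_prev <- gkl
  }

  dead <- which(colSums(W) == 0)
  if (length(dead))
    warning(sprintf("signature(s) %s collapsed to zero weight (effective rank %d < K)",
                    paste(dead, collapse = ", "), K - length(dead)))

  structure(
    list(W = W, H = H, K = as.integer(K), phi = phi,
         gkl_trace = gkl_trace, n_iter = length(gkl_trace),
         converged = converged, tol = tol, seed = as.integer(seed),
         batches = batches, dead_signatures = dead,
         warm_start = list(n_init = n_init, n_iter = n_warm_iter,
                           init = ws$init, gkl_all = ws$gkl_all),
         cutoff = cutoff, smooth_every = smooth_every),
    class = "nnmf_fit")
}

#' @export
print.nnmf_fit <- function(x, ...) {
  cat(sprintf(
    "Neighborhood NMF fit: %d cells x %d genes, K = %d, phi = %g\n",
    nrow(x$W), ncol(x$H), x$K, x$phi))
  cat(sprintf("  %d iteration(s), %s (tol %g); final GKL %.6g\n",
              x$n_iter, if (x$converged) "converged" else "NOT converged",
              x$tol, utils::tail(x$gkl_trace, 1)))
  if (length(x$dead_signatures))
    cat(sprintf("  dead signatures: %s\n",
                paste(x$dead_signatures, collapse = ", ")))
  invisible(x)
}

#' Akaike information criterion for a Poisson factorization
#'
#' Because the Poisson log-likelihood equals the negative GKL divergence up
#' to a term not involving the factors, the AIC can be written directly in
#' terms of the divergence:
#' \eqn{\mathrm{AIC} = 2 D(V \| WH) + 2\, n_{prm}} with
#' \eqn{n_{prm} = NK + KM}, the total number of entries in W and H.
#'
#' @inheritParams gkl_divergence
#' @return AIC value (smaller is better across K).
#' @export
nnmf_aic <- function(V, W, H) {
  if (inherits(W, "nnmf_fit") && missing(H)) {
    H <- W$H
    W <- W$W
  }
  n_prm <- nrow(W) * ncol(W) + nrow(H) * ncol(H)
  2 * gkl_divergence(V, W, H) + 2 * n_prm
}

#' Choose the number of signatures by AIC
#'
#' Fits NNMF for every candidate K with a shared seed policy (identical
#' warm-start seeds across K, so AIC differences reflect the rank rather
#' than initialization luck) and returns the AIC curve with its argmin.
#' Ties are broken toward the smaller K. A fit whose W contains all-zero
#' columns is recorded with its effective rank (< K).
#'
#' @inheritParams fit_nnmf
#' @param k_grid candidate numbers of signatures.
#' @param keep_fits keep the fitted models in the result (default `TRUE`).
#' @param ... further arguments passed to [fit_nnmf()].
#' @return An object of class `nnmf_scan`: `k_grid`, `aic_values`,
#'   `n_prm_values`, `effective_rank`, `best_k` and (optionally) `fits`.
#' @export
select_k <- function(V, X = NULL, k_grid, phi = NULL, phi_grid = NULL,
                     keep_fits = TRUE, ...) {
  if (length(k_grid) < 1L) stop("k_grid must be non-empty")
  if (any(k_grid > min(dim(V)))) stop("every K must be <= min(N, M)")
  if (is.null(phi) && !is.null(X)) {
    # estimate phi once so every K sees the same kernel
    if (is.null(phi_grid)) phi_grid <- default_phi_grid(X)
    phi <- select_length_scale(V, X, phi_grid)$phi
  }
  fits <- lapply(k_grid, function(K) fit_nnmf(V, X, K = K, phi = phi, ...))
  aic_values <- vapply(fits, function(f) nnmf_aic(V, f$W, f$H), numeric(1))
  n_prm_values <- nrow(V) * k_grid + k_grid * ncol(V)
  effective_rank <- vapply(fits, function(f) sum(colSums(f$W) > 0), numeric(1))
  best_k <- k_grid[order(aic_values, k_grid)[1L]]
  structure(
    list(k_grid = as.integer(k_grid), aic_values = aic_values,
         n_prm_values = n_prm_values, effective_rank = effective_rank,
         best_k = as.integer(best_k), phi = phi,
         fits = if (keep_fits) fits),
    class = "nnmf_scan")
}

#' @export
print.nnmf_scan <- function(x, ...) {
  cat("AIC scan over the number of signatures:\n")
  print(data.frame(K = x$k_grid, AIC = x$aic_values,
                   n_prm = x$n_prm_values,
                   effective_rank = x$effective_rank))
  cat(sprintf("best K = %d\n", x$best_k))
  invisible(x)
}
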