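# Synthetic spatial transcriptomics with known ground truth. Every
# recovery test in the package runs on this generator, so no external
# downloads are needed.
#
# The default spatial contrast (field_sd = 0.4 on the log scale, a ~2.5-fold
# activity range across a tissue) is calibrated so the generator behaves the
# way the methods assume spatial data behave: signature fields smooth at the
# generating length scale, recoverable by the fit, and with a neighborhood
# prediction-error curve whose minimum tracks that length scale. Stronger
# contrast pushes the prediction-error optimum to smaller neighborhoods
# (curvature bias dominates); weaker contrast leaves too little spatial
# signal to recover.

#' Simulate spatially smooth Poisson counts
#'
#' Generates a dataset from exactly the model the fit assumes: cell
#' locations uniform on the unit hypercube, K latent activity fields made
#' by Gaussian-kernel smoothing of white noise at length scale `phi_true`
#' (standardized, then passed through an exponential link so the fields
#' are strictly positive and right-skewed like real expression), gene
#' signatures drawn row-wise from a sparse symmetric Dirichlet, and counts
#' \eqn{V_{nm} \sim \mathrm{Poisson}((W_{true} H_{true})_{nm})}. The
#' weight matrix is scaled so the mean total count per cell is
#' `mean_depth` (the rows of `H_true` sum to one, so cell depth equals the
#' row sum of `W_true`).
#'
#' A field whose smoothed noise is exactly constant (the `phi_true = Inf`
#' limit) is kept constant rather than standardized.
#'
#' @param N number of cells; `M` number of genes; `K` number of signatures.
#' @param M see `N`.
#' @param K see `N`.
#' @param phi_true generating length scale on the unit hypercube
#'   (default 0.08).
#' @param mean_depth mean total transcript count per cell (default 200).
#' @param sparsity concentration of the symmetric Dirichlet for the rows
#'   of `H_true`; smaller is sparser (default 0.1).
#' @param field_sd standard deviation of the latent log-activity fields
#'   (default 0.4; see the package vignette for the calibration).
#' @param d spatial dimension, 1, 2 or 3 (default 2).
#' @param seed integer seed; two calls with equal arguments are identical.
#' @return An object of class `synthetic_dataset`: `V` (integer counts,
#'   N x M), `X` (N x d), `W_true`, `H_true` (row-stochastic), `phi_true`,
#'   `seed` and the generator parameters.
#' @export
simulate_spatial_counts <- function(N, M, K, phi_true = 0.08,
                                    mean_depth = 200, sparsity = 0.1,
                                    field_sd = 0.4, d = 2L, seed = 1L) {
  if (N < 1L || M < 1L || K < 1L) stop("N, M, K must be positive")
  if (!(d %in% 1:3)) stop("d must be 1, 2 or 3")
  if (is.na(phi_true) || phi_true <= 0) stop("phi_true must be positive")
  if (mean_depth <= 0 || sparsity <= 0 || field_sd <= 0)
    stop("mean_depth, sparsity and field_sd must be positive")
  withr::with_seed(seed, {
    X <- matrix(stats::runif(N * d), N, d)
    colnames(X) <- c("x", "y", "z")[seq_len(d)]
    S_rn <- gaussian_kernel(X, phi_true, cutoff = Inf, sparse = FALSE)$S_rn
    fields <- vapply(seq_len(K), function(k) {
      f <- as.vector(S_rn %*% stats::rnorm(N))
      s <- stats::sd(f)
      if (s < 1e-12) rep(0, N) else (f - mean(f)) / s
    }, numeric(N))
    W_true <- exp(field_sd * fields)
    W_true <- W_true * (mean_depth / mean(rowSums(W_true)))
    H_true <- row_normalize(matrix(stats::rgamma(K * M, shape = sparsity), K, M))
    lambda <- W_true %*% H_true
    V <- matrix(stats::rpois(N * M, lambda), N, M)
  })
  rownames(V) <- rownames(X) <- rownames(W_true) <- sprintf("cell_%d", seq_len(N))
  colnames(V) <- colnames(H_true) <- sprintf("gene_%d", seq_len(M))
  structure(
    list(V = V, X = X, W_true = W_true, H_true = H_true,
         phi_true = phi_true, seed = as.integer(seed),
         params = list(N = N, M = M, K = K, mean_depth = mean_depth,
                       sparsity = sparsity, field_sd = field_sd, d = d)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic spatial counts: %d cells x %d genes, K = %d, phi_true = %g, mean depth %g (seed %d)\n",
    p$N, p$M, p$K, x$phi_true, p$mean_depth, x$seed))
  invisible(x)
}

#' Simulate counts with planted discrete spatial domains
#'
#' Generates tissue with `n_domains` contiguous regions (Voronoi cells of
#' random centers on the unit square), each carrying its own mixture
#' profile over the K signatures; cells inherit their domain's profile up
#' to a mild per-cell depth fluctuation, and counts are Poisson as in
#' [simulate_spatial_counts()]. With more domains than signatures, several
#' domains necessarily share a dominant signature, so a per-cell argmax
#' labeling cannot separate them while clustering on the full weight
#' vector can — the structure that makes hard clustering on W informative
#' on layered tissue.
#'
#' @inheritParams simulate_spatial_counts
#' @param n_domains number of planted domains (typically > K).
#' @param depth_cv coefficient of variation of per-cell depth (default 0.2).
#' @return An object of class `synthetic_dataset` with the additional
#'   fields `domains` (length-N 1-based labels), `centers` and `profiles`
#'   (n_domains x K mixture profiles).
#' @export
simulate_domain_counts <- function(N, M, K, n_domains, mean_depth = 150,
                                   sparsity = 0.1, depth_cv = 0.2, d = 2L,
                                   seed = 1L) {
  if (N < 1L || M < 1L || K < 1L || n_domains < 1L)
    stop("N, M, K, n_domains must be positive")
  if (!(d %in% 1:3)) stop("d must be 1, 2 or 3")
  withr::with_seed(seed, {
    X <- matrix(stats::runif(N * d), N, d)
    colnames(X) <- c("x", "y", "z")[seq_len(d)]
    centers <- matrix(stats::runif(n_domains * d), n_domains, d)
    domains <- apply(X, 1L, function(p)
      which.min(colSums((t(centers) - p)^2)))
    profiles <- matrix(stats::rgamma(n_domains * K, shape = 1), n_domains, K)
    profiles <- profiles / rowSums(profiles)
    shape <- 1 / depth_cv^2
    depth <- mean_depth * stats::rgamma(N, shape = shape, rate = shape)
    W_true <- profiles[domains, , drop = FALSE] * depth
    H_true <- row_normalize(matrix(stats::rgamma(K * M, shape = sparsity), K, M))
    V <- matrix(stats::rpois(N * M, W_true %*% H_true), N, M)
  })
  rownames(V) <- rownames(X) <- rownames(W_true) <- sprintf("cell_%d", seq_len(N))
  colnames(V) <- colnames(H_true) <- sprintf("gene_%d", seq_len(M))
  structure(
    list(V = V, X = X, W_true = W_true, H_true = H_true,
         domains = as.integer(domains), centers = centers,
         profiles = profiles, phi_true = NA_real_, seed = as.integer(seed),
         params = list(N = N, M = M, K = K, n_domains = n_domains,
                       mean_depth = mean_depth, sparsity = sparsity,
                       depth_cv = depth_cv, d = d)),
    class = "synthetic_dataset")
}

# every permutation of 1..n as rows (n <= 8 keeps this tractable)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

cosine_similarity_rows <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1
  (A / na) %*% t(B / nb)
}

#' Match estimated signatures to ground truth
#'
#' Finds the one-to-one assignment of estimated to true signatures that
#' maximizes the total cosine similarity between matched rows: exhaustively
#' over all permutations for K <= 8, and by maximum-weight bipartite
#' matching for larger K.
#'
#' @param H_est estimated signature matrix (K x M).
#' @param H_true true signature matrix, same shape.
#' @return A list with `permutation` (entry k is the true signature matched
#'   to estimated signature k), `similarities` (matched cosine
#'   similarities, in estimated-signature order) and `mean_similarity`.
#' @export
match_signatures <- function(H_est, H_true) {
  H_est <- as.matrix(H_est); H_true <- as.matrix(H_true)
  if (!all(dim(H_est) == dim(H_true))) stop("shape mismatch")
  K <- nrow(H_est)
  C <- cosine_similarity_rows(H_est, H_true)
  if (K <= 8L) {
    perms <- all_permutations(K)
    scores <- apply(perms, 1L, function(p) sum(C[cbind(seq_len(K), p)]))
    perm <- perms[which.max(scores), ]
  } else {
    # complete bipartite graph; shift weights so the optimum is a perfect
    # matching (cosine similarities can be 0)
    edges <- as.vector(t(cbind(rep(seq_len(K), each = K),
                               K + rep(seq_len(K), times = K))))
    g <- igraph::make_bipartite_graph(c(rep(FALSE, K), rep(TRUE, K)), edges)
    w <- as.vector(t(C)) + 2
    m <- igraph::max_bipartite_match(g, weights = w)
    perm <- as.integer(m$matching[seq_len(K)]) - K
  }
  sims <- C[cbind(seq_len(K), perm)]
  list(permutation = as.integer(perm), similarities = sims,
       mean_similarity = mean(sims))
}
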