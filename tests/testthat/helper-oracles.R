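# Independent scalar-loop oracles. These deliberately avoid the package's
# vectorized code paths: everything is an explicit elementwise loop over the
# printed formulas, so agreement is evidence and not tautology.

gkl_oracle <- function(V, W, H) {
  V <- as.matrix(V)
  s <- 0
  for (n in seq_len(nrow(V))) {
    for (m in seq_len(ncol(V))) {
      wh <- sum(W[n, ] * H[, m])
      v <- V[n, m]
      if (v > 0) s <- s + v * log(v) - v * log(wh)
      s <- s - v + wh
    }
  }
  s
}

update_h_oracle <- function(V, W, H) {
  V <- as.matrix(V)
  K <- nrow(H); M <- ncol(H)
  out <- matrix(0, K, M)
  for (k in seq_len(K)) {
    for (m in seq_len(M)) {
      acc <- 0
      for (n in seq_len(nrow(V))) {
        wh <- sum(W[n, ] * H[, m])
        r <- if (V[n, m] == 0) 0 else V[n, m] / wh
        acc <- acc + W[n, k] * r
      }
      out[k, m] <- H[k, m] * acc
    }
  }
  for (k in seq_len(K)) {
    rs <- sum(out[k, ])
    if (rs > 0) out[k, ] <- out[k, ] / rs
  }
  out
}

update_w_oracle <- function(V, W, H) {
  V <- as.matrix(V)
  N <- nrow(W); K <- ncol(W)
  out <- matrix(0, N, K)
  for (n in seq_len(N)) {
    for (k in seq_len(K)) {
      acc <- 0
      for (m in seq_len(ncol(V))) {
        wh <- sum(W[n, ] * H[, m])
        r <- if (V[n, m] == 0) 0 else V[n, m] / wh
        acc <- acc + r * H[k, m]
      }
      out[n, k] <- W[n, k] * acc
    }
  }
  out
}

smoothing_oracle <- function(S, W) {
  # per-row weighted average with explicitly renormalized kernel rows
  S <- as.matrix(S)
  out <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(nrow(W))) {
    w <- S[i, ] / sum(S[i, ])
    for (k in seq_len(ncol(W))) out[i, k] <- sum(w * W[, k])
  }
  out
}

reweight_oracle <- function(H, epsilon = 1e-12) {
  out <- H * 0
  for (k in seq_len(nrow(H))) {
    for (i in seq_len(ncol(H))) {
      competitors <- H[-k, i]
      out[k, i] <- H[k, i] * log(1 + H[k, i] / max(max(competitors), epsilon))
    }
  }
  out
}

aic_oracle <- function(V, W, H) {
  2 * gkl_oracle(V, W, H) + 2 * (nrow(W) * ncol(W) + nrow(H) * ncol(H))
}

# brute-force leave-self-out neighborhood prediction error, per-cell loop
length_scale_error_oracle <- function(V, X, phi, mode = "squared") {
  V <- as.matrix(V)
  N <- nrow(V)
  P <- matrix(0, N, ncol(V))
  for (i in seq_len(N)) {
    w <- numeric(N)
    for (j in seq_len(N)) {
      if (j != i) w[j] <- exp(-sum((X[i, ] - X[j, ])^2) / phi^2)
    }
    if (sum(w) > 0) P[i, ] <- colSums(V * (w / sum(w)))
  }
  if (mode == "squared") sum((V - P)^2) else sum(V - P)
}

random_instance <- function(N, M, K, seed) {
  withr::with_seed(seed, {
    V <- matrix(rpois(N * M, lambda = 3), N, M)
    W <- matrix(runif(N * K, 0.1, 1), N, K)
    H <- matrix(runif(K * M, 0.1, 1), K, M)
  })
  list(V = V, W = W, H = row_normalize(H))
}
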