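# Poisson-NMF primitives: the GKL objective, the multiplicative updates for
# the signature matrix H and the weight matrix W, and row normalization.
#
# Counts V may be a base matrix or a Matrix::sparseMatrix; W and H are always
# dense base matrices. The elementwise ratio V / (WH) follows the 0/0 = 0
# convention (zero counts are inert), while V > 0 over (WH) = 0 is a hard
# error: the GKL divergence is infinite there and silently clamping it would
# hide model collapse.

is_sparse <- function(A) methods::is(A, "sparseMatrix")

stored_entries <- function(A) if (is_sparse(A)) A@x else A

assert_counts <- function(V) {
  if (!(is.matrix(V) || is_sparse(V)))
    stop("counts must be a base matrix or a sparse Matrix")
  x <- stored_entries(V)
  if (length(x) && (any(!is.finite(x)) || any(x < 0)))
    stop("count matrix must have finite, nonnegative entries")
  invisible(V)
}

assert_factor_shapes <- function(V, W, H) {
  if (nrow(W) != nrow(V) || ncol(H) != ncol(V) || ncol(W) != nrow(H))
    stop(sprintf(
      "shape mismatch: V is %dx%d, W is %dx%d, H is %dx%d",
      nrow(V), ncol(V), nrow(W), ncol(W), nrow(H), ncol(H)))
  invisible(NULL)
}

# nonzero entries of V as triplets (works for dense and sparse storage)
count_triplets <- function(V) {
  if (is_sparse(V)) {
    tr <- Matrix::mat2triplet(V)
    keep <- tr$x != 0
    list(i = tr$i[keep], j = tr$j[keep], x = tr$x[keep])
  } else {
    nz <- which(V != 0)
    idx <- arrayInd(nz, dim(V))
    list(i = idx[, 1L], j = idx[, 2L], x = V[nz])
  }
}

# (WH)_{ij} evaluated only at the requested index pairs
wh_at <- function(W, H, i, j) {
  rowSums(W[i, , drop = FALSE] * t(H)[j, , drop = FALSE])
}

#' Generalized Kullback-Leibler divergence between counts and a factorization
#'
#' Computes \eqn{D(V \| WH) = \sum_{n,m} \{ V_{nm} \log V_{nm} -
#' V_{nm} \log (WH)_{nm} - V_{nm} + (WH)_{nm} \}} with the convention
#' \eqn{0 \log 0 = 0}. Minimizing this divergence in \eqn{(W, H)} is
#' equivalent to maximizing the Poisson likelihood of the counts under the
#' rate matrix \eqn{WH}.
#'
#' @param V nonnegative count matrix (N cells x M genes), dense or sparse.
#' @param W nonnegative weight matrix (N x K).
#' @param H nonnegative signature matrix (K x M).
#' @return A nonnegative scalar; 0 exactly when `V == W %*% H` elementwise.
#'   An error is raised if any positive count sits where the reconstruction
#'   is zero (infinite divergence).
#' @examples
#' W <- matrix(c(1, 2), 2, 1)
#' H <- matrix(c(0.5, 0.5), 1, 2)
#' gkl_divergence(W %*% H, W, H) # 0
#' @export
gkl_divergence <- function(V, W, H) {
  assert_counts(V)
  assert_factor_shapes(V, W, H)
  tr <- count_triplets(V)
  wh <- wh_at(W, H, tr$i, tr$j)
  if (any(wh == 0))
    stop("reconstruction WH is zero where V > 0: GKL divergence is infinite")
  # total sum of WH without forming it: sum_k colSums(W)_k * rowSums(H)_k
  total_wh <- sum(colSums(W) * rowSums(H))
  sum(tr$x * (log(tr$x) - log(wh))) - sum(tr$x) + total_wh
}

# elementwise V / (WH), nonzero only where V is nonzero (0/0 = 0 convention);
# returned in the same storage class as V
kl_ratio <- function(V, W, H) {
  assert_factor_shapes(V, W, H)
  if (is_sparse(V)) {
    tr <- count_triplets(V)
    wh <- wh_at(W, H, tr$i, tr$j)
    if (any(wh == 0))
      stop("reconstruction WH is zero where V > 0: update is undefined")
    Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x / wh, dims = dim(V))
  } else {
    WH <- W %*% H
    if (any(V > 0 & WH == 0))
      stop("reconstruction WH is zero where V > 0: update is undefined")
    R <- V / WH
    R[V == 0] <- 0
    R
  }
}

#' Multiplicative update of the signature matrix H
#'
#' One GKL multiplicative step
#' \eqn{H \leftarrow \mathrm{rnorm}(H \otimes (W^\top (V \oslash WH)))},
#' where \eqn{\oslash} is the elementwise ratio with \eqn{0/0 = 0} and
#' `rnorm` rescales every row to sum to one. Because the rows of H are kept
#' on the simplex, the companion W update needs no denominator and the pair
#' of updates never increases the GKL divergence.
#'
#' Zeros in H are preserved exactly (multiplicative updates cannot revive
#' them).
#'
#' @inheritParams gkl_divergence
#' @return Updated K x M signature matrix with rows summing to 1.
#' @export
update_h <- function(V, W, H) {
  R <- kl_ratio(V, W, H)
  row_normalize(H * as.matrix(Matrix::crossprod(W, R)))
}

#' Multiplicative update of the weight matrix W
#'
#' One GKL multiplicative step
#' \eqn{W \leftarrow W \otimes ((V \oslash WH) H^\top)}. With the rows of H
#' summing to one this is the standard Poisson-NMF update for W (the usual
#' denominator \eqn{\mathbf{1} H^\top} is identically 1). Zeros in W,
#' including all-zero rows from empty cells, are preserved without producing
#' NaN.
#'
#' @inheritParams gkl_divergence
#' @return Updated N x K nonnegative weight matrix.
#' @export
update_w <- function(V, W, H) {
  R <- kl_ratio(V, W, H)
  W * as.matrix(Matrix::tcrossprod(R, H))
}

#' Row normalization
#'
#' Rescales every row of a nonnegative matrix to sum to one. Rows that sum
#' to zero are returned unchanged as all-zero rows; downstream fitting
#' detects such dead rows rather than inventing mass for them.
#'
#' @param A nonnegative matrix (dense or sparse).
#' @return Matrix of the same class whose nonzero rows sum to 1.
#' @examples
#' row_normalize(matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE))
#' @export
row_normalize <- function(A) {
  x <- stored_entries(A)
  if (length(x) && any(x < 0)) stop("row_normalize: negative entries")
  rs <- Matrix::rowSums(A)
  if (any(!is.finite(rs))) stop("row_normalize: non-finite rows")
  scale <- ifelse(rs == 0, 0, 1 / rs)
  if (is_sparse(A)) Matrix::Diagonal(x = scale) %*% A else A * scale
}
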