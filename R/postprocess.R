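# Signature interpretation: TF-IDF-style gene reweighting, top-gene tables,
# K-means hard clusters, top-signature labels and cell-type enrichment.

#' Reweight gene signatures toward signature-unique genes
#'
#' Rescales every entry of the signature matrix by how unique the gene is
#' to that signature, in the spirit of TF-IDF:
#' \deqn{H^{new}_{ki} = H_{ki} \cdot \log\!\left(1 +
#'   \frac{H_{ki}}{\max_{j \ne k} H_{ji}}\right).}
#' A gene carried equally by all signatures is scaled by \eqn{\log 2}; a
#' gene expressed in a single signature is amplified by
#' \eqn{\log(1 + H_{ki}/\epsilon)} and floats to the top of the ranking.
#' Zeros map to zeros.
#'
#' @param H nonnegative signature matrix (K x M) with K >= 2.
#' @param epsilon floor for the max-over-competitors denominator, for genes
#'   absent from every other signature (default 1e-12).
#' @return K x M matrix of rescaled weights.
#' @export
reweight_genes <- function(H, epsilon = 1e-12) {
  H <- as.matrix(H)
  if (nrow(H) < 2L) stop("reweighting needs at least two signatures")
  if (any(H < 0)) stop("H must be nonnegative")
  K <- nrow(H)
  # per column: max over the other rows = overall max, except at the (first)
  # argmax row where it is the runner-up
  max_other <- apply(H, 2L, function(v) {
    o <- order(v, decreasing = TRUE)
    out <- rep(v[o[1L]], K)
    out[o[1L]] <- if (K >= 2L) v[o[2L]] else 0
    out
  })
  H * log1p(H / pmax(max_other, epsilon))
}

#' Ranked top genes per signature
#'
#' Ranks genes within each signature by their reweighted value (see
#' [reweight_genes()]), descending, with ties broken by the original
#' weight and then by gene identifier. Both the original and the rescaled
#' weight are reported, matching the "weighted and unweighted ranking"
#' style of signature tables.
#'
#' @param H signature matrix (K x M) or an `nnmf_fit`.
#' @param n number of genes per signature (default 10; at most M).
#' @param epsilon passed to [reweight_genes()].
#' @return A data.frame with columns `signature`, `rank`, `gene`,
#'   `original_weight`, `rescaled_weight`.
#' @export
top_genes <- function(H, n = 10L, epsilon = 1e-12) {
  if (inherits(H, "nnmf_fit")) H <- H$H
  H <- as.matrix(H)
  if (n > ncol(H)) stop("n exceeds the number of genes")
  genes <- colnames(H)
  if (is.null(genes)) genes <- sprintf("gene_%d", seq_len(ncol(H)))
  R <- reweight_genes(H, epsilon = epsilon)
  out <- lapply(seq_len(nrow(H)), function(k) {
    o <- order(-R[k, ], -H[k, ], genes)[seq_len(n)]
    data.frame(signature = k, rank = seq_len(n), gene = genes[o],
               original_weight = H[k, o], rescaled_weight = R[k, o],
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Hard clusters from K-means on the weight vectors
#'
#' Applies standard K-means to the rows of W (each cell's signature weight
#' vector), returning one discrete label per cell. Compared with taking the
#' per-cell top signature this uses the whole weight profile, which on
#' layered tissue recovers domains markedly better. Deterministic given
#' `seed`; the best of `n_restarts` runs by within-cluster sum of squares
#' is kept.
#'
#' @param W weight matrix (N x K) or an `nnmf_fit`.
#' @param n_clusters number of clusters (at most the number of distinct
#'   rows of W; degenerate W triggers a warning and a reduced cluster
#'   count).
#' @param seed integer seed.
#' @param n_restarts K-means restarts (default 10).
#' @return Integer vector of 1-based cluster labels, length N.
#' @export
hard_clusters <- function(W, n_clusters, seed = 1L, n_restarts = 10L) {
  if (inherits(W, "nnmf_fit")) W <- W$W
  W <- as.matrix(W)
  if (n_clusters > nrow(W)) stop("more clusters than cells")
  n_distinct <- nrow(unique(W))
  if (n_distinct < n_clusters) {
    warning(sprintf(
      "only %d distinct weight vector(s); reducing the cluster count from %d",
      n_distinct, n_clusters))
    n_clusters <- n_distinct
  }
  km <- withr::with_seed(seed,
    stats::kmeans(W, centers = n_clusters, nstart = n_restarts,
                  iter.max = 100L))
  as.integer(km$cluster)
}

#' Top signature per cell
#'
#' The per-cell argmax over signature weights: the crudest hard labeling of
#' the soft clusters. Ties go to the lowest signature index.
#'
#' @param W weight matrix (N x K) or an `nnmf_fit`.
#' @return Integer vector of 1-based signature indices, length N.
#' @export
top_signature <- function(W) {
  if (inherits(W, "nnmf_fit")) W <- W$W
  max.col(as.matrix(W), ties.method = "first")
}

#' Fold enrichment of cell types across signatures
#'
#' For each signature k and cell type t, the share of the signature's
#' weight mass carried by type-t cells divided by the overall frequency of
#' type t; 1 means no enrichment. With `x` a weight matrix the mass is the
#' soft weight; with `x` a label vector each cell contributes unit mass to
#' its labeled cluster.
#'
#' For every signature the type-frequency-weighted mean of the fold
#' enrichments is exactly 1.
#'
#' @param x weight matrix (N x K), `nnmf_fit`, or a length-N vector of
#'   hard cluster labels.
#' @param cell_types length-N vector of cell-type labels (no missing
#'   values).
#' @return Signatures x cell-types matrix of fold enrichments.
#' @export
fold_enrichment <- function(x, cell_types) {
  if (inherits(x, "nnmf_fit")) x <- x$W
  if (length(cell_types) == 0L || anyNA(cell_types))
    stop("every cell needs a cell-type label")
  ct <- factor(cell_types)
  if (any(table(ct) == 0L)) stop("empty cell type")
  if (is.matrix(x) || is_sparse(x)) {
    W <- as.matrix(x)
  } else {
    lab <- factor(x)
    W <- outer(lab, levels(lab), "==") * 1
    colnames(W) <- levels(lab)
  }
  if (nrow(W) != length(ct)) stop("cell types and weights disagree on cell count")
  # mass of each type within each signature: K x T
  mass <- t(rowsum(W, ct))               # signatures x types
  share <- mass / rowSums(mass)
  freq <- as.vector(table(ct)) / length(ct)
  fe <- sweep(share, 2L, freq, "/")
  dimnames(fe) <- list(signature = colnames(W) %||% seq_len(nrow(fe)),
                       cell_type = levels(ct))
  fe
}

`%||%` <- function(a, b) if (is.null(a)) b else a
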