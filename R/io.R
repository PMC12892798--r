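# File I/O: counts (MatrixMarket or delimited text), coordinates, and
# serialized fit results.

#' Read a count matrix
#'
#' Reads cells x genes counts from MatrixMarket coordinate files
#' (`Matrix::readMM`; 1-based indices per the standard) or delimited text.
#' Delimited files may carry a header row of gene identifiers and a first
#' column of cell identifiers (detected when that column is non-numeric).
#' Rows are assumed to be cells; pass `transpose = TRUE` for genes x cells
#' files. Negative or non-finite entries are rejected.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mtx"`, `"tsv"` or `"csv"`.
#' @param transpose transpose after reading (for genes x cells files).
#' @param min_gene_fraction drop genes expressed (count > 0) in less than
#'   this fraction of cells, after any transposition; 0 keeps everything.
#'   A value of 0.1 reproduces the common "expressed in at least ten
#'   percent of observations" filter.
#' @param cell_ids,gene_ids optional identifier vectors (or paths to
#'   one-identifier-per-line files), mainly for MatrixMarket input which
#'   stores none.
#' @return Count matrix with cell row names and gene column names; sparse
#'   (`dgCMatrix`) when density is below 20%, dense otherwise.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv", "csv"),
                        transpose = FALSE, min_gene_fraction = 0,
                        cell_ids = NULL, gene_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    V <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  } else {
    df <- utils::read.delim(path, sep = if (format == "csv") "," else "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) >= 2L && !is.numeric(df[[1L]])) {
      rn <- as.character(df[[1L]])
      df <- df[, -1L, drop = FALSE]
    } else rn <- NULL
    V <- as.matrix(df)
    if (!is.numeric(V)) stop(sprintf("non-numeric entries in %s", path))
    rownames(V) <- rn
  }
  if (transpose) V <- Matrix::t(V)
  assert_counts(V)

  id_vec <- function(x) {
    if (is.null(x)) NULL
    else if (length(x) == 1L && file.exists(x)) readLines(x)
    else as.character(x)
  }
  cell_ids <- id_vec(cell_ids); gene_ids <- id_vec(gene_ids)
  if (!is.null(cell_ids)) {
    if (length(cell_ids) != nrow(V)) stop("cell_ids length does not match the cell count")
    rownames(V) <- cell_ids
  }
  if (!is.null(gene_ids)) {
    if (length(gene_ids) != ncol(V)) stop("gene_ids length does not match the gene count")
    colnames(V) <- gene_ids
  }
  if (is.null(rownames(V))) rownames(V) <- sprintf("cell_%d", seq_len(nrow(V)))
  if (is.null(colnames(V))) colnames(V) <- sprintf("gene_%d", seq_len(ncol(V)))

  if (min_gene_fraction > 0) V <- filter_genes(V, min_gene_fraction)

  dens <- if (is_sparse(V)) length(V@x) / prod(dim(V)) else mean(V != 0)
  if (!is_sparse(V) && dens < 0.2) V <- methods::as(Matrix::Matrix(V, sparse = TRUE), "CsparseMatrix")
  if (is_sparse(V) && dens >= 0.2) V <- as.matrix(V)
  V
}

#' Drop rarely expressed genes
#'
#' Keeps genes expressed (count > 0) in at least `min_fraction` of cells;
#' genes below the threshold are removed.
#'
#' @param V count matrix (cells x genes).
#' @param min_fraction minimum fraction of cells expressing the gene.
#' @return The filtered count matrix.
#' @export
filter_genes <- function(V, min_fraction) {
  assert_counts(V)
  frac <- Matrix::colMeans(V > 0)
  V[, frac >= min_fraction, drop = FALSE]
}

#' Write a count matrix as TSV
#'
#' Cells x genes with a header of gene identifiers and a leading `cell_id`
#' column; round-trips through [read_counts()].
#'
#' @param V count matrix.
#' @param path output path.
#' @export
write_counts <- function(V, path) {
  V <- as.matrix(V)
  df <- data.frame(cell_id = rownames(V) %||% sprintf("cell_%d", seq_len(nrow(V))),
                   V, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spatial coordinates
#'
#' Reads a delimited table with coordinate columns `x`, `y`[, `z`] (in that
#' order), an optional leading identifier column (detected when
#' non-numeric, or named `cell_id`), and an optional `slice` column. When
#' `cell_ids` is supplied the rows are realigned to that order by
#' identifier, and any mismatch is a hard error: coordinates must line up
#' row-for-row with the count matrix.
#'
#' @param path file path (TSV by default, CSV by extension).
#' @param cell_ids optional cell identifiers, typically
#'   `rownames(counts)`, used to check and realign row order.
#' @param d optionally require this spatial dimension; an error is raised
#'   if the file provides fewer axes (e.g. a 3D analysis over a 2D table).
#' @return Numeric N x d matrix with cell row names and, when a slice
#'   column is present, a `"slices"` attribute.
#' @export
read_coords <- function(path, cell_ids = NULL, d = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- NULL
  if ("cell_id" %in% names(df)) {
    ids <- as.character(df[["cell_id"]])
    df[["cell_id"]] <- NULL
  } else if (ncol(df) >= 2L && !is.numeric(df[[1L]])) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  slices <- NULL
  if ("slice" %in% names(df)) {
    slices <- df[["slice"]]
    df[["slice"]] <- NULL
  }
  axes <- intersect(c("x", "y", "z"), names(df))
  X <- as.matrix(if (length(axes)) df[, axes, drop = FALSE] else df)
  if (!is.numeric(X) || any(!is.finite(X))) stop("coordinates must be finite numbers")
  if (!is.null(d) && ncol(X) < d)
    stop(sprintf("requested %dD coordinates but %s provides only %d axis/axes",
                 d, path, ncol(X)))
  if (!is.null(ids)) rownames(X) <- ids
  if (!is.null(cell_ids)) {
    if (is.null(ids)) {
      if (nrow(X) != length(cell_ids))
        stop(sprintf("coordinate table has %d rows but counts have %d cells",
                     nrow(X), length(cell_ids)))
    } else {
      if (!setequal(ids, cell_ids) || length(ids) != length(cell_ids))
        stop("coordinate identifiers do not match the count matrix cells")
      ord <- match(cell_ids, ids)
      X <- X[ord, , drop = FALSE]
      if (!is.null(slices)) slices <- slices[ord]
    }
  }
  if (!is.null(slices)) attr(X, "slices") <- slices
  X
}

#' Serialize a fit to a directory
#'
#' Writes `W.tsv` (cells x signatures), `H.tsv` (signatures x genes),
#' `batches.tsv` (cell_id, batch) and `meta.json` (K, phi, seed, tol,
#' iterations, convergence flag and the full GKL trace). The directory can
#' be read back with [read_fit()] and is sufficient to regenerate all
#' interpretation tables.
#'
#' @param fit an `nnmf_fit`.
#' @param dir output directory (created if needed).
#' @param cell_ids,gene_ids optional identifiers for the TSV headers.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir, cell_ids = NULL, gene_ids = NULL) {
  stopifnot(inherits(fit, "nnmf_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cell_ids <- cell_ids %||% rownames(fit$W) %||% sprintf("cell_%d", seq_len(nrow(fit$W)))
  gene_ids <- gene_ids %||% colnames(fit$H) %||% sprintf("gene_%d", seq_len(ncol(fit$H)))
  W <- fit$W
  dimnames(W) <- list(cell_ids, sprintf("signature_%d", seq_len(ncol(W))))
  utils::write.table(data.frame(cell_id = cell_ids, W, check.names = FALSE),
                     file.path(dir, "W.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  H <- fit$H
  dimnames(H) <- list(sprintf("signature_%d", seq_len(nrow(H))), gene_ids)
  utils::write.table(data.frame(signature = rownames(H), H, check.names = FALSE),
                     file.path(dir, "H.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(cell_id = cell_ids,
                                batch = fit$batches$assignment),
                     file.path(dir, "batches.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(K = fit$K, phi = fit$phi, seed = fit$seed, tol = fit$tol,
               n_iter = fit$n_iter, converged = fit$converged,
               cutoff = fit$cutoff, smooth_every = fit$smooth_every,
               dead_signatures = fit$dead_signatures,
               warm_start = fit$warm_start, gkl_trace = fit$gkl_trace,
               batch_seed = fit$batches$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' Read a serialized fit
#'
#' @param dir directory written by [write_fit()].
#' @return An `nnmf_fit` (without warm-start matrices).
#' @export
read_fit <- function(dir) {
  Wdf <- utils::read.delim(file.path(dir, "W.tsv"), check.names = FALSE)
  W <- as.matrix(Wdf[, -1L, drop = FALSE])
  rownames(W) <- Wdf[[1L]]
  Hdf <- utils::read.delim(file.path(dir, "H.tsv"), check.names = FALSE)
  H <- as.matrix(Hdf[, -1L, drop = FALSE])
  rownames(H) <- Hdf[[1L]]
  bdf <- utils::read.delim(file.path(dir, "batches.tsv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(
    list(W = W, H = H, K = as.integer(meta$K), phi = meta$phi,
         gkl_trace = as.numeric(meta$gkl_trace),
         n_iter = as.integer(meta$n_iter), converged = meta$converged,
         tol = meta$tol, seed = as.integer(meta$seed),
         batches = batch_partition(bdf$batch,
                                   seed = meta$batch_seed %||% NA_integer_),
         dead_signatures = as.integer(meta$dead_signatures),
         warm_start = meta$warm_start, cutoff = meta$cutoff,
         smooth_every = meta$smooth_every),
    class = "nnmf_fit")
}

#' Write the synthetic-data triplet
#'
#' Writes `V.mtx` (MatrixMarket), `coords.tsv`, and a `truth/` directory
#' with `W_true.tsv`, `H_true.tsv` and `params.json`.
#'
#' @param sim a `synthetic_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(sim$V, sparse = TRUE), file.path(dir, "V.mtx"))
  writeLines(rownames(sim$V), file.path(dir, "cell_ids.txt"))
  writeLines(colnames(sim$V), file.path(dir, "gene_ids.txt"))
  utils::write.table(data.frame(cell_id = rownames(sim$X), sim$X,
                                check.names = FALSE),
                     file.path(dir, "coords.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(cell_id = rownames(sim$W_true), sim$W_true,
                                check.names = FALSE),
                     file.path(dir, "truth", "W_true.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(signature = seq_len(nrow(sim$H_true)),
                                sim$H_true, check.names = FALSE),
                     file.path(dir, "truth", "H_true.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(sim$params, list(phi_true = sim$phi_true,
                                          seed = sim$seed)),
                       file.path(dir, "truth", "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
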