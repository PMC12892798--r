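# Spatial batching: per-batch kernels bound the memory of the smoothing
# step, since a single kernel over N cells needs N^2 entries.

#' Batch partition of cells
#'
#' Light container recording which batch each cell belongs to. Batches are
#' numbered 1..B in order of creation.
#'
#' @param assignment integer-like vector giving the batch of each cell.
#' @param seed integer seed used to build the partition, if any.
#' @return An object of class `batch_partition` with elements `assignment`,
#'   `sizes`, `n_batches` and `seed`.
#' @export
batch_partition <- function(assignment, seed = NA_integer_) {
  assignment <- as.integer(assignment)
  if (length(assignment) == 0L || anyNA(assignment))
    stop("every cell needs a batch label")
  n_batches <- max(assignment)
  if (min(assignment) < 1L) stop("batch labels must be positive integers")
  structure(
    list(assignment = assignment,
         sizes = tabulate(assignment, nbins = n_batches),
         n_batches = n_batches,
         seed = seed),
    class = "batch_partition")
}

#' @export
print.batch_partition <- function(x, ...) {
  cat(sprintf("Batch partition: %d cells in %d batch(es); sizes: %s\n",
              length(x$assignment), x$n_batches,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Spatially compact batches (groupondist)
#'
#' Partitions cells into spatially compact batches by repeatedly picking a
#' random not-yet-assigned anchor cell and grouping it with its
#' `batch_size - 1` nearest not-yet-assigned neighbors (the anchor is part
#' of its own batch). The procedure stops when fewer than `batch_size`
#' cells remain; those form the final, smaller batch. Distance ties are
#' broken by cell index so the result is fully determined by `seed`.
#'
#' @param X coordinate matrix (N x d).
#' @param batch_size requested batch size (20000 is a workable size for
#'   million-cell slices; use the largest size that fits memory).
#' @param seed integer seed for anchor sampling.
#' @return A [batch_partition()].
#' @export
groupondist <- function(X, batch_size, seed = 1L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("coordinates must be finite")
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L) stop("batch_size must be >= 1")
  N <- nrow(X)
  assignment <- integer(N)
  withr::with_seed(seed, {
    remaining <- seq_len(N)
    b <- 0L
    while (length(remaining) > batch_size) {
      anchor <- remaining[sample.int(length(remaining), 1L)]
      d2 <- colSums((t(X[remaining, , drop = FALSE]) - X[anchor, ])^2)
      pick <- remaining[order(d2, remaining)[seq_len(batch_size)]]
      b <- b + 1L
      assignment[pick] <- b
      remaining <- remaining[!(remaining %in% pick)]
    }
    if (length(remaining)) assignment[remaining] <- b + 1L
  })
  batch_partition(assignment, seed = seed)
}

#' One batch per tissue slice
#'
#' Multi-slice data get one batch per distinct slice label, so a smoothing
#' kernel is built separately for each slice and no kernel entry ever
#' crosses slices. Batches are numbered in order of first appearance of
#' each label; cell order within a batch follows input order.
#'
#' @param slice_labels length-N vector of slice labels (no missing values).
#' @return A [batch_partition()].
#' @export
slice_batches <- function(slice_labels) {
  if (length(slice_labels) == 0L || anyNA(slice_labels))
    stop("every cell needs a slice label")
  batch_partition(as.integer(factor(slice_labels, levels = unique(slice_labels))))
}

#' Stored kernel entries for a set of batch sizes
#'
#' The smoothing kernel for a batch of n cells has n^2 entries; batching
#' replaces one large kernel by per-batch kernels, storing
#' \eqn{\sum_b n_b^2} entries instead of \eqn{(\sum_b n_b)^2}.
#'
#' @param sizes vector of positive batch sizes.
#' @return The exact total entry count, as a double (counts above
#'   `.Machine$integer.max` are exact up to 2^53).
#' @examples
#' kernel_entry_count(50627)            # one batch of the full dataset
#' kernel_entry_count(c(24594, 26033))  # about half as many entries
#' @export
kernel_entry_count <- function(sizes) {
  if (length(sizes) == 0L || any(sizes < 1)) stop("sizes must be positive")
  sum(as.numeric(sizes)^2)
}
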