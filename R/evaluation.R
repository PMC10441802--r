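#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same
#' observations (Hubert-Arabie form, computed from the contingency table):
#' 1 for identical partitions up to relabelling, 0 in expectation for random
#' labellings.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' High-certainty subset of an averaged clustering
#'
#' Observations whose maximum allocation probability exceeds a threshold;
#' restricting inference to this subset confines cluster-based conclusions
#' to points with low model-based uncertainty.
#'
#' @param alloc N x K allocation matrix, or a \code{bmaclust} fit.
#' @param threshold strict lower bound on the maximum allocation
#'   probability, in (0, 1); default 0.8.
#' @return list with \code{indices} (integer vector) and \code{proportion}
#'   (share of observations retained). An empty subset raises a warning.
#' @export
high_certainty_subset <- function(alloc, threshold = 0.8) {
  if (inherits(alloc, "bmaclust")) alloc <- alloc$allocations
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  alloc <- as_allocation(alloc)
  pmax_ <- apply(alloc, 1, max)
  idx <- which(pmax_ > threshold)
  if (length(idx) == 0L) warning("no observations exceed the threshold")
  list(indices = idx, proportion = length(idx) / nrow(alloc))
}
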