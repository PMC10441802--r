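#' Consensus matrix of an ensemble of clustering solutions
#'
#' Element-wise weighted average of per-model similarity matrices,
#' \eqn{C = \sum_m \hat W_m S^m}, a posterior similarity matrix of pairwise
#' co-assignment probabilities under the model ensemble. Because each
#' similarity matrix has unit diagonal and the weights are a convex
#' combination, the consensus inherits symmetry, entries in \[0, 1\] and a
#' unit diagonal.
#'
#' @param sims list of N x N similarity matrices, one per model (see
#'   \code{\link{allocation_to_similarity}}).
#' @param weights a \code{bma_weights} object from
#'   \code{\link{normalise_weights}}, or a bare numeric vector of weights
#'   aligned with \code{sims}. Weights summing to 1 only within 1e-6 are
#'   renormalised; larger deviations are an error.
#' @return N x N consensus similarity matrix.
#' @export
consensus_matrix <- function(sims, weights) {
  if (!is.list(sims) || length(sims) == 0L)
    stop("'sims' must be a non-empty list of similarity matrices")
  w <- if (inherits(weights, "bma_weights")) weights$weight else as.numeric(weights)
  if (length(w) != length(sims))
    stop("need exactly one weight per similarity matrix")
  if (abs(sum(w) - 1) > 1e-6)
    stop("weights must sum to 1 (got ", format(sum(w)), ")")
  w <- w / sum(w)
  sims <- lapply(sims, validate_similarity)
  n <- nrow(sims[[1]])
  if (!all(vapply(sims, nrow, integer(1)) == n))
    stop("all similarity matrices must share the same dimension")
  C <- matrix(0, n, n)
  for (m in seq_along(sims)) C <- C + w[m] * sims[[m]]
  diag(C) <- 1
  validate_similarity(C, tol = 1e-8)
}
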