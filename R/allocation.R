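#' Validate and normalise a cluster allocation matrix
#'
#' An allocation matrix holds, for each of N observations (rows), the
#' probability of membership in each of K clusters (columns). Rows must lie on
#' the probability simplex: entries in \[0, 1\] summing to one. Hard clusterers
#' produce binary allocations with a single 1 per row; soft clusterers (e.g. a
#' Gaussian mixture model or fuzzy c-means) produce genuinely probabilistic
#' rows.
#'
#' Rows whose sums deviate from 1 by no more than \code{tol} are renormalised;
#' larger deviations signal a malformed input and raise an error.
#'
#' @param x numeric matrix (or object coercible to one), N x K.
#' @param model_id optional label identifying the model that produced the
#'   allocation; stored as the \code{"model_id"} attribute.
#' @param tol row-sum tolerance beyond which the input is rejected.
#' @return the validated N x K allocation matrix, rows summing to exactly 1.
#' @examples
#' as_allocation(matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE), "toy")
#' @export
as_allocation <- function(x, model_id = NULL, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("allocation matrix must have at least one row and one column")
  if (anyNA(x) || any(!is.finite(x)))
    stop("allocation matrix contains missing or non-finite values")
  if (any(x < -tol) || any(x > 1 + tol))
    stop("allocation probabilities must lie in [0, 1]")
  rs <- rowSums(x)
  if (any(abs(rs - 1) > tol))
    stop("allocation rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  x <- pmin(pmax(x, 0), 1)
  x <- x / rowSums(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("cluster_", seq_len(ncol(x)))
  if (!is.null(model_id)) attr(x, "model_id") <- as.character(model_id)
  x
}

#' Test whether an allocation matrix is hard (binary)
#'
#' @param alloc allocation matrix.
#' @param tol numeric tolerance.
#' @return logical scalar: does every row place all its mass on one cluster?
#' @export
is_hard_allocation <- function(alloc, tol = 1e-8) {
  all(abs(alloc) < tol | abs(alloc - 1) < tol)
}

#' Pairwise similarity matrix of a clustering solution
#'
#' Converts an N x K allocation matrix into the N x N matrix of pairwise
#' co-assignment probabilities: entry (i, j) is the probability that
#' observations i and j fall in the same cluster under the model, i.e. the
#' inner product of allocation rows i and j, with the diagonal set to 1.
#' Representing solutions at this level makes them comparable across models
#' regardless of the number or labelling of clusters.
#'
#' @param alloc N x K allocation matrix (validated through
#'   \code{\link{as_allocation}}).
#' @param tol row-sum tolerance passed to validation.
#' @return N x N symmetric similarity matrix with unit diagonal.
#' @examples
#' A <- labels_to_allocation(c(1, 1, 2), 2)
#' allocation_to_similarity(A)
#' @export
allocation_to_similarity <- function(alloc, tol = 1e-8) {
  alloc <- as_allocation(alloc, tol = tol)
  S <- tcrossprod(alloc)
  diag(S) <- 1
  S <- (S + t(S)) / 2   # exact symmetry against BLAS rounding
  S
}

#' Harden a soft allocation (crisp projection)
#'
#' Assigns each observation wholly to the cluster in which it has the highest
#' allocation probability. Ties are broken to the lowest cluster index, so the
#' projection is deterministic.
#'
#' @param alloc N x K allocation matrix.
#' @return hard N x K allocation matrix.
#' @seealso \code{\link{crisp_labels}} for the integer labels.
#' @export
crisp_projection <- function(alloc) {
  alloc <- as_allocation(alloc)
  k <- ncol(alloc)
  labels_to_allocation(max.col(alloc, ties.method = "first"), k)
}

#' Integer cluster labels from an allocation matrix
#'
#' @param alloc N x K allocation matrix.
#' @return integer vector of length N, the argmax cluster of each row (ties to
#'   the lowest index).
#' @export
crisp_labels <- function(alloc) {
  max.col(as_allocation(alloc), ties.method = "first")
}

#' Hard allocation matrix from integer labels
#'
#' @param labels integer vector with values in 1..k.
#' @param k number of clusters (columns); may exceed \code{max(labels)}, in
#'   which case the surplus columns are all zero.
#' @return hard N x k allocation matrix.
#' @export
labels_to_allocation <- function(labels, k = max(labels)) {
  if (length(labels) == 0L) stop("empty label vector")
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1L) || any(labels > k))
    stop("labels must be integers in 1..k")
  A <- matrix(0, nrow = length(labels), ncol = k,
              dimnames = list(NULL, paste0("cluster_", seq_len(k))))
  A[cbind(seq_along(labels), labels)] <- 1
  A
}

# Validate an N x N similarity / consensus matrix.
validate_similarity <- function(S, tol = 1e-10) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (any(abs(S - t(S)) > tol)) stop("similarity matrix must be symmetric")
  if (any(S < -tol) || any(S > 1 + tol))
    stop("similarity entries must lie in [0, 1]")
  if (any(abs(diag(S) - 1) > tol))
    stop("similarity diagonal must equal 1")
  S
}

#' Read and write allocation matrices as delimited text
#'
#' Allocation matrices are exchanged as headered CSV with an observation-id
#' first column and one column per cluster. Similarity and consensus matrices
#' are square CSV with matching row and column observation ids.
#'
#' @param alloc allocation matrix to write.
#' @param file path to a CSV file.
#' @param ids observation identifiers; defaults to \code{obs_1..obs_N}.
#' @return \code{read_allocation} returns a validated allocation matrix;
#'   the writers return \code{file} invisibly.
#' @name allocation_io
#' @export
write_allocation <- function(alloc, file, ids = NULL) {
  alloc <- as_allocation(alloc)
  if (is.null(ids)) ids <- paste0("obs_", seq_len(nrow(alloc)))
  utils::write.csv(data.frame(id = ids, alloc, check.names = FALSE),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname allocation_io
#' @param model_id optional model label attached on read.
#' @export
read_allocation <- function(file, model_id = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- NULL
  as_allocation(m, model_id = model_id)
}

#' @rdname allocation_io
#' @param sim similarity matrix to write.
#' @export
write_similarity <- function(sim, file, ids = NULL) {
  sim <- validate_similarity(sim)
  if (is.null(ids)) ids <- paste0("obs_", seq_len(nrow(sim)))
  dimnames(sim) <- list(ids, ids)
  utils::write.csv(as.data.frame(sim), file, row.names = TRUE)
  invisible(file)
}

#' @rdname allocation_io
#' @export
read_similarity <- function(file) {
  df <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  validate_similarity(as.matrix(df))
}

#' Long-format table of a similarity matrix
#'
#' Heatmap-ready (i, j, value) export of a similarity or consensus matrix.
#'
#' @param sim N x N similarity matrix.
#' @return data frame with columns \code{i}, \code{j}, \code{value}.
#' @export
similarity_long <- function(sim) {
  sim <- validate_similarity(sim)
  n <- nrow(sim)
  data.frame(i = rep(seq_len(n), times = n),
             j = rep(seq_len(n), each = n),
             value = as.vector(sim))
}
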