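#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster sums of squares, each scaled by
#' its degrees of freedom:
#' \deqn{CH = \frac{BGSS/(K-1)}{WGSS/(N-K)},}
#' with \eqn{BGSS = \sum_k n_k \|c_k - \bar c\|^2} and
#' \eqn{WGSS = \sum_k \sum_{x \in g_k} \|x - c_k\|^2}. Higher is better:
#' compact, well-separated clusters score high. This is the standard form of
#' the index and the package default for model weighting; see
#' \code{\link{calinski_harabasz_pairwise}} for a variant whose numerator sums
#' squared pairwise centroid distances instead.
#'
#' @param features N x D numeric matrix.
#' @param labels integer cluster labels of length N; at least two non-empty
#'   clusters are required.
#' @return positive scalar score (to be maximised).
#' @export
calinski_harabasz <- function(features, labels) {
  ss <- .cluster_ss(features, labels)
  if (ss$wgss <= 0)
    stop("Calinski-Harabasz undefined: zero within-cluster variation")
  (ss$bgss / (ss$K - 1)) / (ss$wgss / (ss$N - ss$K))
}

#' Pairwise-centroid variant of the Calinski-Harabasz index
#'
#' As \code{\link{calinski_harabasz}} but with numerator
#' \eqn{\sum_{j \ne k} n_k d^2(c_j, c_k) / (K-1)}: the separation term sums
#' squared distances between every ordered pair of centroids, weighted by the
#' receiving cluster's size, rather than squared distances to the grand
#' centroid. Provided for completeness; the standard form is the default.
#'
#' @inheritParams calinski_harabasz
#' @return positive scalar score (to be maximised).
#' @export
calinski_harabasz_pairwise <- function(features, labels) {
  ss <- .cluster_ss(features, labels)
  if (ss$wgss <= 0)
    stop("Calinski-Harabasz undefined: zero within-cluster variation")
  cd2 <- as.matrix(stats::dist(ss$centers))^2
  num <- sum(ss$sizes * rowSums(cd2))  # sum_k n_k sum_{j != k} d^2(c_j, c_k)
  (num / (ss$K - 1)) / (ss$wgss / (ss$N - ss$K))
}

# Shared sums-of-squares pieces for the CH family.
.cluster_ss <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  lev <- sort(unique(labels))
  K <- length(lev)
  N <- nrow(features)
  if (K < 2) stop("at least two non-empty clusters are required")
  if (N <= K) stop("need more observations than clusters")
  centers <- t(vapply(lev, function(l) colMeans(features[labels == l, , drop = FALSE]),
                      numeric(ncol(features))))
  grand <- colMeans(features)
  sizes <- as.vector(table(factor(labels, levels = lev)))
  bgss <- sum(sizes * rowSums(sweep(centers, 2, grand)^2))
  wgss <- sum(vapply(seq_len(K), function(i) {
    sum(sweep(features[labels == lev[i], , drop = FALSE], 2, centers[i, ])^2)
  }, numeric(1)))
  list(centers = centers, sizes = sizes, bgss = bgss, wgss = wgss, K = K, N = N)
}

#' S_Dbw index
#'
#' Sum of an intra-cluster variance (scatter) term and an inter-cluster
#' density term, \eqn{S\_Dbw = Scat(K) + Dens\_bw(K)}. The scatter term is the
#' mean, over clusters, of the ratio of the Euclidean norm of each cluster's
#' per-dimension variance vector to the norm of the dataset variance vector.
#' The density term compares the number of points within a neighbourhood of
#' each pair's centroid midpoint against the density around the two centroids
#' themselves; the neighbourhood radius is the mean cluster variance norm
#' \eqn{\tau = (1/K)\sum_k \|\sigma(C_k)\|}. Lower is better. Variances use
#' the population (1/N) convention.
#'
#' When no points fall within \eqn{\tau} of either centroid of a pair, that
#' pair's density ratio is taken as 0 (the clusters are so tight that the
#' midpoint region is empty too).
#'
#' @inheritParams calinski_harabasz
#' @return non-negative scalar score (to be minimised).
#' @export
s_dbw <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  lev <- sort(unique(labels))
  K <- length(lev)
  if (K < 2) stop("at least two non-empty clusters are required")

  popvar <- function(x) {
    mu <- colMeans(x)
    colSums(sweep(x, 2, mu)^2) / nrow(x)
  }
  sigma_d <- sqrt(sum(popvar(features)^2))
  if (sigma_d <= 0) stop("S_Dbw undefined: zero dataset variance")

  centers <- t(vapply(lev, function(l) colMeans(features[labels == l, , drop = FALSE]),
                      numeric(ncol(features))))
  sigma_k <- vapply(lev, function(l) {
    sqrt(sum(popvar(features[labels == l, , drop = FALSE])^2))
  }, numeric(1))

  scat <- mean(sigma_k / sigma_d)
  tau <- mean(sigma_k)  # density neighbourhood radius

  n_within <- function(pts, centre) {
    sum(sqrt(rowSums(sweep(pts, 2, centre)^2)) <= tau)
  }

  dens <- 0
  for (k in seq_len(K)) {
    for (j in seq_len(K)) {
      if (j == k) next
      union_pts <- features[labels %in% c(lev[k], lev[j]), , drop = FALSE]
      mid <- (centers[k, ] + centers[j, ]) / 2
      num <- n_within(union_pts, mid)
      den <- max(n_within(features[labels == lev[k], , drop = FALSE], centers[k, ]),
                 n_within(features[labels == lev[j], , drop = FALSE], centers[j, ]))
      if (den > 0) dens <- dens + num / den
      else if (num > 0) dens <- dens + 1  # degenerate: empty centres, occupied midpoint
    }
  }
  dens <- dens / (K * (K - 1))

  scat + dens
}

# --- index registry ---------------------------------------------------------

.civi_registry <- new.env(parent = emptyenv())

#' Register a clustering internal validation index
#'
#' The registry maps an index name to a scoring function
#' \code{function(features, labels)} and a direction ("maximise" or
#' "minimise") saying whether larger or smaller scores indicate better
#' clustering. Built-in indices: \code{"ch"} (Calinski-Harabasz, maximise,
#' the default weighting index), \code{"ch_pairwise"} (its pairwise-centroid
#' variant, maximise), \code{"sdbw"} (S_Dbw, minimise) and
#' \code{"silhouette"} (mean silhouette width, maximise). Additional indices
#' can be registered by the user.
#'
#' @param name index name.
#' @param fun scoring function taking \code{(features, labels)}.
#' @param direction \code{"maximise"} or \code{"minimise"}.
#' @return \code{register_civi} returns \code{name} invisibly;
#'   \code{civi_direction} returns the registered direction;
#'   \code{civi_names} the registered index names.
#' @export
register_civi <- function(name, fun, direction = c("maximise", "minimise")) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, list(fun = fun, direction = direction), envir = .civi_registry)
  invisible(name)
}

#' @rdname register_civi
#' @export
civi_names <- function() sort(ls(.civi_registry))

#' @rdname register_civi
#' @export
civi_direction <- function(name) .civi_lookup(name)$direction

.civi_lookup <- function(name) {
  if (!exists(name, envir = .civi_registry, inherits = FALSE))
    stop("unknown validation index '", name, "'; registered: ",
         paste(civi_names(), collapse = ", "))
  get(name, envir = .civi_registry, inherits = FALSE)
}

#' Score a clustering solution with a validation index
#'
#' Computes the named internal validation index for an allocation matrix on a
#' feature matrix. Soft allocations are first hardened by crisp projection
#' (each observation assigned to its highest-probability cluster), so that
#' every index sees integer labels.
#'
#' @param index registered index name (see \code{\link{register_civi}}).
#' @param features N x D feature matrix.
#' @param alloc N x K allocation matrix or an integer label vector.
#' @return scalar index value.
#' @export
compute_civi <- function(index, features, alloc) {
  entry <- .civi_lookup(index)
  labels <- if (is.matrix(alloc)) crisp_labels(alloc) else as.integer(alloc)
  entry$fun(as.matrix(features), labels)
}

# --- weight normalisation ---------------------------------------------------

#' Normalised model weights from validation-index scores
#'
#' Turns raw per-model index scores \eqn{W_m} into normalised weights
#' \eqn{\hat W_m} approximating each model's posterior probability under equal
#' model priors. For an index that is maximised,
#' \eqn{\hat W_m = W_m / \sum_{m'} W_{m'}}; for one that is minimised the
#' reciprocals are normalised instead, \eqn{\hat W_m = W_m^{-1} / \sum_{m'}
#' W_{m'}^{-1}}. With equal priors 1/M the normalised weight is itself the
#' approximate posterior model probability.
#'
#' @param raw numeric vector of raw index scores, one per model. Must be
#'   finite; non-negative under \code{"maximise"} (scores are treated as
#'   evidence masses), strictly positive under \code{"minimise"}.
#' @param direction whether the underlying index is maximised or minimised.
#' @param model_ids optional model labels.
#' @param index optional index name recorded alongside the weights.
#' @return object of class \code{bma_weights}: a data frame with columns
#'   \code{model}, \code{raw} and \code{weight} (summing to 1), carrying the
#'   index name and direction as attributes.
#' @examples
#' normalise_weights(c(100, 300), "maximise")
#' normalise_weights(c(2, 2, 4), "minimise")
#' @export
normalise_weights <- function(raw, direction = c("maximise", "minimise"),
                              model_ids = NULL, index = NULL) {
  direction <- match.arg(direction)
  raw <- as.numeric(raw)
  if (length(raw) == 0L) stop("no scores supplied")
  if (any(!is.finite(raw))) stop("raw scores must be finite")
  if (direction == "maximise") {
    if (any(raw < 0))
      stop("negative scores cannot be normalised under 'maximise'")
    if (sum(raw) <= 0) stop("all scores are zero; weights undefined")
    w <- raw / sum(raw)
  } else {
    if (any(raw <= 0))
      stop("scores must be strictly positive under 'minimise'")
    w <- (1 / raw) / sum(1 / raw)
  }
  if (is.null(model_ids)) model_ids <- paste0("model_", seq_along(raw))
  out <- data.frame(model = as.character(model_ids), raw = raw, weight = w,
                    stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  attr(out, "index") <- index
  class(out) <- c("bma_weights", "data.frame")
  out
}

#' @export
print.bma_weights <- function(x, ...) {
  idx <- attr(x, "index")
  cat("Model weights",
      if (!is.null(idx)) paste0(" (index: ", idx, ", ", attr(x, "direction"), "d)"),
      ":\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
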