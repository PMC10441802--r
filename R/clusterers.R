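#' Names of the built-in clustering algorithms
#'
#' The nine-algorithm ensemble used by the simulation harness, plus Ward
#' hierarchical clustering.
#'
#' @return character vector of algorithm names accepted by
#'   \code{\link{run_clusterer}}.
#' @export
bma_algorithms <- function() {
  c("hc_average", "diana", "kmeans", "pam", "affinity_propagation",
    "spectral", "gmm", "som", "fuzzy_cmeans")
}

#' Run a clustering algorithm and return its allocation matrix
#'
#' Uniform adapter around standard clustering backends, each returning an
#' N x k allocation matrix suitable for ensemble averaging. Hard algorithms
#' (hierarchical clustering with average or Ward linkage, divisive
#' hierarchical clustering, k-means, partitioning around medoids, affinity
#' propagation, spectral clustering, self-organising map) yield binary
#' allocations; soft algorithms (Gaussian mixture model, fuzzy c-means)
#' yield probabilistic allocations. All adapters are deterministic given
#' \code{seed}.
#'
#' Backends: \code{stats::hclust} (\code{hc_average}, \code{hc_ward}),
#' \code{cluster::diana}, \code{stats::kmeans}, \code{cluster::pam},
#' \code{kernlab::specc} (with a median-heuristic RBF bandwidth),
#' \code{mclust::Mclust}, \code{class::batchSOM} on a 1 x k grid, and
#' \code{e1071::cmeans}. Affinity propagation does not take k natively: the
#' damped message-passing iteration identifies exemplars, whose centres are
#' then agglomerated (average linkage) down to k clusters; if fewer than k
#' exemplars emerge, the surplus columns are empty and a warning is raised.
#'
#' @param algorithm one of \code{\link{bma_algorithms}} or \code{"hc_ward"}.
#' @param features N x D numeric feature matrix.
#' @param k number of clusters (at least 2, less than N).
#' @param seed integer seed (optional).
#' @param ... passed through to the backend.
#' @return N x k allocation matrix with \code{model_id} set to
#'   \code{algorithm}.
#' @examples
#' d <- simulate_clusters(3, 30, 2, sep_val = 0.5, seed = 1)
#' A <- run_clusterer("kmeans", d$features, 3, seed = 1)
#' table(crisp_labels(A), d$labels)
#' @export
run_clusterer <- function(algorithm, features, k, seed = NULL, ...) {
  algorithm <- match.arg(algorithm, c(bma_algorithms(), "hc_ward"))
  features <- as.matrix(features)
  if (anyNA(features) || any(!is.finite(features)))
    stop("features must be finite")
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2")
  if (nrow(features) <= k) stop("need more observations than clusters")
  if (!is.null(seed)) set.seed(seed)

  A <- switch(algorithm,
    hc_average = .hard_alloc(stats::cutree(
      stats::hclust(stats::dist(features), method = "average"), k), k),
    hc_ward = .hard_alloc(stats::cutree(
      stats::hclust(stats::dist(features), method = "ward.D2"), k), k),
    diana = .hard_alloc(stats::cutree(stats::as.hclust(
      cluster::diana(stats::dist(features), diss = TRUE)), k), k),
    kmeans = .hard_alloc(stats::kmeans(features, centers = k, nstart = 10,
                                       iter.max = 50, ...)$cluster, k),
    pam = .hard_alloc(cluster::pam(features, k = k, pamonce = 5,
                                   keep.diss = FALSE,
                                   keep.data = FALSE, ...)$clustering, k),
    affinity_propagation = .hard_alloc(.ap_labels(features, k, ...), k),
    spectral = .hard_alloc(.spectral_labels(features, k, ...), k),
    gmm = mclust::Mclust(features, G = k, verbose = FALSE, ...)$z,
    som = .hard_alloc(.som_labels(features, k, ...), k),
    fuzzy_cmeans = e1071::cmeans(features, centers = k, ...)$membership
  )
  as_allocation(A, model_id = algorithm)
}

.hard_alloc <- function(labels, k) {
  if (length(unique(labels)) < k)
    warning("algorithm produced fewer than k non-empty clusters")
  labels_to_allocation(labels, k)
}

# Affinity propagation: damped message passing on negative squared
# Euclidean distances (median preference), then agglomeration of exemplars
# down to k groups by average linkage on the exemplar feature vectors.
.ap_labels <- function(features, k, damping = 0.9, max_iter = 300,
                       conv_iter = 30) {
  S <- -as.matrix(stats::dist(features))^2
  diag(S) <- stats::median(S[upper.tri(S)])
  msg <- .ap_messages(S, damping, as.integer(max_iter), as.integer(conv_iter))
  ex <- msg$exemplars
  assignment <- msg$assignment
  if (length(ex) < k) {
    warning("affinity propagation found only ", length(ex),
            " exemplars for k = ", k)
    return(assignment)
  }
  if (length(ex) == k) return(assignment)
  groups <- stats::cutree(stats::hclust(
    stats::dist(features[ex, , drop = FALSE]), method = "average"), k)
  groups[assignment]
}

# Spectral clustering with an explicit median-heuristic RBF bandwidth; the
# automatic bandwidth search in the backend is costly and stochastic.
.spectral_labels <- function(features, k, sigma = NULL, subsample = 300) {
  if (is.null(sigma)) {
    idx <- sample.int(nrow(features), min(nrow(features), subsample))
    d2 <- stats::dist(features[idx, , drop = FALSE])^2
    sigma <- 1 / stats::median(d2[d2 > 0])
  }
  sc <- kernlab::specc(features, centers = k, kernel = "rbfdot",
                       kpar = list(sigma = sigma))
  as.integer(sc@.Data)
}

# Self-organising map on a 1 x k grid: each map node is one cluster. The
# radius schedule anneals to zero so the final epochs are pure vector
# quantisation; without them the smoothed codebook drags nodes together.
.som_labels <- function(features, k, radii = c(2, 1, 0.5, 0)) {
  grid <- class::somgrid(xdim = 1, ydim = k, topo = "rectangular")
  som <- class::batchSOM(features, grid, radii = radii)
  d <- as.matrix(stats::dist(rbind(som$codes, features)))
  d <- d[-(seq_len(k)), seq_len(k), drop = FALSE]
  lab <- max.col(-d, ties.method = "first")
  if (length(unique(lab)) < k) warning("self-organising map left empty nodes")
  lab
}
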