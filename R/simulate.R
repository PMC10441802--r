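#' Quantile-based separation index between two clusters
#'
#' Projects both clusters onto the direction that best separates them and
#' measures the normalised gap between the upper \eqn{1-\alpha/2} quantile of
#' the lower cluster and the lower \eqn{\alpha/2} quantile of the upper
#' cluster:
#' \deqn{J = \frac{q_L(B) - q_U(A)}{q_U(B) - q_L(A)},}
#' where A is the cluster with the smaller projected mean. The index lies in
#' (-1, 1): positive values mean a visible gap between the clusters, negative
#' values mean their \eqn{1-\alpha} bodies overlap. The projection direction
#' starts at the difference of cluster means (optimal for spherical clusters
#' of equal spread) and is refined numerically to maximise the index.
#'
#' For two unit-variance Gaussian clusters whose means are \eqn{\delta}
#' apart, the population index is \eqn{(\delta - 2z)/(\delta + 2z)} with
#' \eqn{z = \Phi^{-1}(1-\alpha/2)}; \code{\link{separation_to_distance}}
#' inverts this relation.
#'
#' @param features_a,features_b feature matrices of the two clusters
#'   (rows = points), with matching column counts.
#' @param alpha tail probability split between the two quantiles;
#'   default 0.05.
#' @param optimise refine the projection direction numerically (default
#'   TRUE); with FALSE the mean-difference direction is used as is.
#' @return scalar separation index.
#' @export
separation_index <- function(features_a, features_b, alpha = 0.05,
                             optimise = TRUE) {
  A <- as.matrix(features_a)
  B <- as.matrix(features_b)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("both clusters must be non-empty")
  if (ncol(A) != ncol(B)) stop("clusters must share the same dimensions")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")

  index_for <- function(w) {
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) return(-1)
    w <- w / nw
    pa <- drop(A %*% w)
    pb <- drop(B %*% w)
    if (mean(pa) > mean(pb)) { tmp <- pa; pa <- pb; pb <- tmp }
    qua <- stats::quantile(pa, 1 - alpha / 2, names = FALSE)
    qla <- stats::quantile(pa, alpha / 2, names = FALSE)
    qub <- stats::quantile(pb, 1 - alpha / 2, names = FALSE)
    qlb <- stats::quantile(pb, alpha / 2, names = FALSE)
    den <- qub - qla
    if (den <= 0) return(NA_real_)
    (qlb - qua) / den
  }

  w0 <- colMeans(B) - colMeans(A)
  if (sqrt(sum(w0^2)) < 1e-12) w0 <- rep(1, ncol(A))
  j0 <- index_for(w0)
  if (is.na(j0)) stop("degenerate projection: zero spread along the direction")
  if (optimise && ncol(A) > 1) {
    opt <- stats::optim(w0, function(w) {
      v <- index_for(w)
      if (is.na(v)) 1 else -v
    }, method = "Nelder-Mead", control = list(maxit = 200))
    if (-opt$value > j0) return(-opt$value)
  }
  j0
}

#' Map a separation index to a between-centre distance
#'
#' Closed-form inverse of the population separation index for spherical
#' unit-variance Gaussian clusters: a target index J corresponds to centre
#' distance \eqn{\delta = 2z(1+J)/(1-J)} with
#' \eqn{z = \Phi^{-1}(1-\alpha/2)}.
#'
#' @param sep_val target separation index in (-1, 1).
#' @param alpha quantile tail probability (default 0.05).
#' @return centre-to-centre distance in units of the cluster standard
#'   deviation.
#' @export
separation_to_distance <- function(sep_val, alpha = 0.05) {
  if (sep_val <= -1 || sep_val >= 1) stop("sep_val must lie in (-1, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  2 * z * (1 + sep_val) / (1 - sep_val)
}

# k vertices of a regular simplex in R^(k-1) with unit edge length:
# rows of the column-normalised Helmert contrast matrix have pairwise
# distance sqrt(2); scale accordingly.
.regular_simplex <- function(k) {
  H <- stats::contr.helmert(k)
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  H / sqrt(2)
}

#' Simulate labelled Gaussian clusters at a controlled separation
#'
#' Draws spherical unit-variance multivariate normal clusters whose centres
#' sit at the vertices of a regular simplex embedded in the first
#' \code{n_clusters - 1} coordinates, scaled so that the population
#' separation index of every cluster pair equals \code{sep_val}
#' (\code{\link{separation_to_distance}}). All pairwise separations are
#' equal by construction, so the nearest-pair separation is unambiguous.
#' Remaining coordinates are pure noise, so raising \code{n_dims} adds
#' dimensions without adding structure.
#'
#' @param n_clusters number of clusters (at least 2).
#' @param points_per_cluster points drawn per cluster.
#' @param n_dims dimensionality; must be at least \code{n_clusters - 1}.
#' @param sep_val target pairwise separation index in (-1, 1).
#' @param seed integer seed (optional).
#' @param alpha quantile tail probability of the separation index.
#' @return list of class \code{bma_simdata} with elements \code{features}
#'   (N x n_dims matrix), \code{labels} (integer vector), \code{centers}
#'   (cluster centres) and \code{spec} (the generating parameters).
#' @examples
#' d <- simulate_clusters(3, 50, 2, sep_val = 0.1, seed = 1)
#' table(d$labels)
#' @export
simulate_clusters <- function(n_clusters = 3, points_per_cluster = 500,
                              n_dims = 2, sep_val = 0.1, seed = NULL,
                              alpha = 0.05) {
  stopifnot(n_clusters >= 2, points_per_cluster >= 1, n_dims >= 1)
  if (n_dims < n_clusters - 1)
    stop("n_dims must be at least n_clusters - 1 to embed the centre simplex")
  if (!is.null(seed)) set.seed(seed)

  delta <- separation_to_distance(sep_val, alpha)
  centers <- matrix(0, n_clusters, n_dims)
  centers[, seq_len(n_clusters - 1)] <- .regular_simplex(n_clusters) * delta

  n <- n_clusters * points_per_cluster
  labels <- rep(seq_len(n_clusters), each = points_per_cluster)
  features <- matrix(stats::rnorm(n * n_dims), n, n_dims) + centers[labels, ]
  colnames(features) <- paste0("dim_", seq_len(n_dims))

  structure(list(features = features, labels = labels, centers = centers,
                 spec = list(n_clusters = n_clusters,
                             points_per_cluster = points_per_cluster,
                             n_dims = n_dims, sep_val = sep_val,
                             alpha = alpha, seed = seed)),
            class = "bma_simdata")
}

#' @export
print.bma_simdata <- function(x, ...) {
  s <- x$spec
  cat("Simulated clusters:", s$n_clusters, "x", s$points_per_cluster,
      "points in", s$n_dims, "dimensions, separation index",
      format(s$sep_val), "\n")
  invisible(x)
}

#' Write / read a simulated dataset as CSV with a JSON sidecar
#'
#' The feature matrix and label column go to \code{file}; the generating
#' parameters go to a \code{.json} sidecar next to it (requires the
#' \pkg{jsonlite} package).
#'
#' @param x a \code{bma_simdata} object.
#' @param file CSV path.
#' @return \code{write_simdata} returns \code{file} invisibly;
#'   \code{read_simdata} returns a \code{bma_simdata} object (without
#'   centres, which are not stored).
#' @export
write_simdata <- function(x, file) {
  stopifnot(inherits(x, "bma_simdata"))
  utils::write.csv(data.frame(x$features, label = x$labels),
                   file, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    sidecar <- paste0(sub("\\.csv$", "", file), ".json")
    jsonlite::write_json(x$spec, sidecar, auto_unbox = TRUE, null = "null")
  }
  invisible(file)
}

#' @rdname write_simdata
#' @export
read_simdata <- function(file) {
  df <- utils::read.csv(file)
  lab <- as.integer(df$label)
  feats <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  spec <- NULL
  sidecar <- paste0(sub("\\.csv$", "", file), ".json")
  if (file.exists(sidecar) && requireNamespace("jsonlite", quietly = TRUE))
    spec <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(list(features = feats, labels = lab, centers = NULL, spec = spec),
            class = "bma_simdata")
}
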