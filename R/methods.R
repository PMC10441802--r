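#' @export
print.bmaclust <- function(x, ...) {
  cat("Model-averaged clustering of", x$n_obs, "observations\n")
  cat("  input models:", paste0(x$input_models$model, " (k=",
                                x$input_models$k, ")", collapse = ", "), "\n")
  cat("  averaged clusters:", x$surviving_clusters,
      if (x$surviving_clusters < x$k_bma)
        paste0("(", x$k_bma - x$surviving_clusters, " emptied of ",
               x$k_bma, " requested)"), "\n")
  cat("  mean allocation uncertainty:", format(mean(x$uncertainty), digits = 3),
      "\n")
  invisible(x)
}

#' Summary of a model-averaged clustering
#'
#' @param object a \code{bmaclust} fit.
#' @param threshold high-certainty allocation-probability threshold used in
#'   the reported proportion.
#' @param ... unused.
#' @return object of class \code{summary.bmaclust} with cluster sizes, model
#'   weights, uncertainty quartiles and the high-certainty proportion.
#' @export
summary.bmaclust <- function(object, threshold = 0.8, ...) {
  hc <- suppressWarnings(high_certainty_subset(object, threshold))
  structure(list(n_obs = object$n_obs,
                 cluster_sizes = table(object$labels),
                 weights = object$weights,
                 uncertainty = stats::quantile(object$uncertainty),
                 mean_uncertainty = mean(object$uncertainty),
                 prop_high_certainty = hc$proportion,
                 threshold = threshold,
                 surviving_clusters = object$surviving_clusters,
                 k_bma = object$k_bma,
                 objective = object$objective,
                 converged = object$converged,
                 iterations = length(object$objective_trace) - 1L),
            class = "summary.bmaclust")
}

#' @export
print.summary.bmaclust <- function(x, ...) {
  cat("Model-averaged clustering:", x$n_obs, "observations,",
      x$surviving_clusters, "clusters\n\n")
  cat("Cluster sizes:\n")
  print(x$cluster_sizes)
  cat("\n")
  print(x$weights)
  cat("\nAllocation uncertainty (1 - max probability):\n")
  print(signif(x$uncertainty, 3))
  cat("\nProportion with allocation probability >", x$threshold, ":",
      format(x$prop_high_certainty, digits = 3), "\n")
  cat("Factorisation objective:", format(x$objective, digits = 6),
      "after", x$iterations, "iterations",
      if (!x$converged) "(not converged)", "\n")
  invisible(x)
}

#' Allocation probabilities of a model-averaged clustering
#'
#' @param object a \code{bmaclust} fit.
#' @param ... unused.
#' @return the averaged N x K allocation matrix.
#' @export
fitted.bmaclust <- function(object, ...) object$allocations

#' Plot a model-averaged clustering
#'
#' Scatter plot of two feature dimensions, coloured by averaged cluster,
#' with point size proportional to allocation uncertainty (larger points =
#' more uncertain, typically at cluster boundaries).
#'
#' @param x a \code{bmaclust} fit.
#' @param features feature matrix; defaults to the one stored in the fit.
#' @param dims which two columns to plot.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @return \code{x}, invisibly.
#' @export
plot.bmaclust <- function(x, features = x$features, dims = c(1, 2), ...) {
  if (is.null(features))
    stop("no stored features; pass 'features' explicitly")
  features <- as.matrix(features)
  graphics::plot(features[, dims[1]], features[, dims[2]],
                 col = x$labels, pch = 19,
                 cex = 0.4 + 1.6 * x$uncertainty,
                 xlab = colnames(features)[dims[1]],
                 ylab = colnames(features)[dims[2]], ...)
  invisible(x)
}
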