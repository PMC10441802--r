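#' Bayesian model averaging of clustering solutions
#'
#' Combines two or more clustering solutions of the same observations into a
#' single probabilistic clustering. The procedure: (1) each input solution is
#' an N x K_m allocation matrix (hard or soft; K_m may differ across models);
#' (2) each is expressed as an N x N pairwise similarity matrix; (3) each
#' model is scored with a clustering internal validation index, and the
#' scores normalised into weights approximating posterior model
#' probabilities under equal priors; (4) the weighted element-wise average
#' of the similarity matrices gives a consensus matrix; (5) symmetric
#' simplex matrix factorisation of the consensus yields the averaged N x
#' k_bma allocation matrix, from which empty clusters are pruned and
#' per-observation uncertainty (one minus the maximum allocation
#' probability) is read off.
#'
#' @param allocations list of N x K_m allocation matrices (see
#'   \code{\link{as_allocation}}, \code{\link{run_clusterer}}). Alternatively
#'   \code{NULL}, with \code{algorithms} naming backends to run internally.
#' @param features N x D feature matrix; required to score each model with
#'   the validation index (and to run \code{algorithms}).
#' @param algorithms optional character vector of backends from
#'   \code{\link{bma_algorithms}} to run on \code{features} at \code{k}
#'   clusters each, used when \code{allocations} is NULL.
#' @param k clusters per algorithm when running \code{algorithms}.
#' @param index validation index used for weighting (default \code{"ch"},
#'   Calinski-Harabasz; see \code{\link{register_civi}}).
#' @param k_bma target number of averaged clusters; defaults to the largest
#'   K_m among the inputs (\code{\link{choose_k_bma}}).
#' @param control an \code{\link{ssmf_control}} object; its \code{seed}
#'   also seeds any internally run algorithms.
#' @param prune drop averaged clusters whose mass falls below
#'   \code{control$mass_threshold} (default TRUE).
#' @param keep_features store \code{features} in the fit for plotting.
#' @return object of class \code{bmaclust}: a list with elements
#'   \code{allocations} (averaged N x K allocation matrix),
#'   \code{labels} (crisp labels), \code{uncertainty}, \code{weights}
#'   (a \code{bma_weights} data frame), \code{consensus},
#'   \code{surviving_clusters}, \code{k_bma}, \code{objective},
#'   \code{objective_trace}, \code{converged}, \code{input_models} and
#'   \code{n_obs}.
#' @examples
#' d <- simulate_clusters(3, 40, 2, sep_val = 0.3, seed = 7)
#' fit <- cluster_bma(features = d$features,
#'                    algorithms = c("kmeans", "hc_average"),
#'                    control = ssmf_control(seed = 7, n_restarts = 2))
#' fit
#' adjusted_rand_index(fit$labels, d$labels)
#' @export
cluster_bma <- function(allocations = NULL, features, algorithms = NULL,
                        k = 3, index = "ch", k_bma = NULL,
                        control = ssmf_control(), prune = TRUE,
                        keep_features = TRUE) {
  features <- as.matrix(features)
  if (is.null(allocations)) {
    if (is.null(algorithms))
      stop("supply either 'allocations' or 'algorithms'")
    allocations <- lapply(seq_along(algorithms), function(i) {
      run_clusterer(algorithms[i], features, k,
                    seed = if (!is.null(control$seed)) control$seed + i)
    })
  }
  if (!is.list(allocations) || length(allocations) < 2L)
    stop("model averaging needs at least two input clustering solutions")
  allocations <- lapply(allocations, as_allocation)
  n <- nrow(features)
  if (!all(vapply(allocations, nrow, integer(1)) == n))
    stop("all allocation matrices must cover the same observations as 'features'")

  ids <- vapply(seq_along(allocations), function(i) {
    id <- attr(allocations[[i]], "model_id")
    if (is.null(id)) paste0("model_", i) else id
  }, character(1))
  ids <- make.unique(ids, sep = "_")

  # steps 2-3: similarity representation and index-based weights
  sims <- lapply(allocations, allocation_to_similarity)
  raw <- vapply(allocations, function(a) compute_civi(index, features, a),
                numeric(1))
  weights <- normalise_weights(raw, civi_direction(index),
                               model_ids = ids, index = index)

  # step 4: consensus matrix
  C <- consensus_matrix(sims, weights)

  # step 5: factorisation, pruning, uncertainty
  input_ks <- vapply(allocations, ncol, integer(1))
  if (is.null(k_bma)) k_bma <- choose_k_bma(input_ks)
  A <- ssmf_factorise(C, k_bma, control)
  obj <- attr(A, "objective")
  trace <- attr(A, "objective_trace")
  conv <- attr(A, "converged")
  surviving <- ncol(A)
  if (prune) {
    A <- prune_empty_clusters(A, control$mass_threshold)
    surviving <- attr(A, "surviving_clusters")
  }

  structure(list(allocations = A,
                 labels = crisp_labels(A),
                 uncertainty = allocation_uncertainty(A),
                 weights = weights,
                 consensus = C,
                 surviving_clusters = surviving,
                 k_bma = as.integer(k_bma),
                 objective = obj,
                 objective_trace = trace,
                 converged = conv,
                 input_models = data.frame(model = ids, k = input_ks),
                 n_obs = n,
                 features = if (keep_features) features else NULL,
                 call = match.call()),
            class = "bmaclust")
}

#' Simulation benchmark of the model-averaged clustering
#'
#' Runs the full simulation protocol: for each condition (dimensionality x
#' separation index) and replicate, simulate three spherical Gaussian
#' clusters of equal size, run the base clustering algorithms at a fixed k,
#' average them with \code{\link{cluster_bma}}, and score the result against
#' the true labels with the adjusted Rand index — overall, and restricted to
#' the high-certainty subset (maximum allocation probability above
#' \code{threshold}).
#'
#' Per-task seeds are derived from \code{seed} with a counter scheme, so the
#' whole study is reproducible and any single replicate can be re-run in
#' isolation (the per-replicate seeds are reported in the replicate table).
#'
#' @param conditions data frame with columns \code{n_dims} and
#'   \code{sep_val}; defaults to the 3 x 3 grid of dimensions 2/10/50 and
#'   separation indices 0.1 / -0.05 / -0.15.
#' @param replicates simulated datasets per condition.
#' @param seed master seed.
#' @param algorithms base clusterers (default \code{\link{bma_algorithms}}).
#' @param n_clusters,points_per_cluster simulated cluster structure
#'   (default 3 clusters of 500 points).
#' @param k clusters requested from every base algorithm.
#' @param index weighting index (default Calinski-Harabasz).
#' @param threshold high-certainty allocation-probability threshold.
#' @param control \code{\link{ssmf_control}} template; its seed field is
#'   overwritten per task.
#' @param verbose print per-replicate progress lines.
#' @return object of class \code{bma_simstudy}: list with \code{summary}
#'   (per-condition means and standard deviations of the full-sample ARI,
#'   high-certainty ARI and high-certainty proportion) and
#'   \code{replicates} (per-replicate values and seeds).
#' @export
run_simulation_study <- function(conditions = NULL, replicates = 10,
                                 seed = 1, algorithms = bma_algorithms(),
                                 n_clusters = 3, points_per_cluster = 500,
                                 k = 3, index = "ch", threshold = 0.8,
                                 control = ssmf_control(), verbose = FALSE) {
  if (is.null(conditions))
    conditions <- expand.grid(n_dims = c(2L, 10L, 50L),
                              sep_val = c(0.1, -0.05, -0.15))
  stopifnot(replicates >= 1, all(c("n_dims", "sep_val") %in% names(conditions)))

  rows <- vector("list", nrow(conditions) * replicates)
  task <- 0L
  for (ci in seq_len(nrow(conditions))) {
    nd <- conditions$n_dims[ci]
    sv <- conditions$sep_val[ci]
    for (r in seq_len(replicates)) {
      task <- task + 1L
      tseed <- (as.integer(seed) * 1000003L + task * 7919L) %% 2147483562L
      t0 <- proc.time()[3]
      d <- simulate_clusters(n_clusters, points_per_cluster, nd,
                             sep_val = sv, seed = tseed)
      ctl <- control
      ctl$seed <- tseed + 500L
      fit <- cluster_bma(features = d$features, algorithms = algorithms,
                         k = k, index = index, control = ctl,
                         keep_features = FALSE)
      ari <- adjusted_rand_index(fit$labels, d$labels)
      hc <- suppressWarnings(high_certainty_subset(fit, threshold))
      ari_hc <- if (length(hc$indices))
        adjusted_rand_index(fit$labels[hc$indices], d$labels[hc$indices])
      else NA_real_
      rows[[task]] <- data.frame(n_dims = nd, sep_val = sv, replicate = r,
                                 seed = tseed, ari = ari,
                                 ari_high_certainty = ari_hc,
                                 prop_high_certainty = hc$proportion,
                                 surviving_clusters = fit$surviving_clusters)
      if (verbose)
        message(sprintf("dims=%d sep=%+.2f rep=%d: ARI %.3f (hc %.3f, prop %.2f) [%.1fs]",
                        nd, sv, r, ari, ari_hc, hc$proportion,
                        proc.time()[3] - t0))
    }
  }
  reps <- do.call(rbind, rows)

  agg <- do.call(rbind, lapply(split(reps, list(reps$n_dims, reps$sep_val),
                                     drop = TRUE), function(g) {
    sdev <- function(x) if (nrow(g) > 1) stats::sd(x) else NA_real_
    data.frame(n_dims = g$n_dims[1], sep_val = g$sep_val[1],
               mean_ari = mean(g$ari), sd_ari = sdev(g$ari),
               mean_ari_high = mean(g$ari_high_certainty),
               sd_ari_high = sdev(g$ari_high_certainty),
               mean_prop_high = mean(g$prop_high_certainty),
               sd_prop_high = sdev(g$prop_high_certainty))
  }))
  agg <- agg[order(-agg$sep_val, agg$n_dims), ]
  rownames(agg) <- NULL

  structure(list(summary = agg, replicates = reps, seed = seed,
                 algorithms = algorithms, index = index,
                 threshold = threshold, call = match.call()),
            class = "bma_simstudy")
}

#' @export
print.bma_simstudy <- function(x, ...) {
  cat("Simulation benchmark:", length(unique(paste(x$replicates$n_dims,
      x$replicates$sep_val))), "conditions x",
      max(x$replicates$replicate), "replicates,",
      length(x$algorithms), "base algorithms, index:", x$index, "\n\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
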