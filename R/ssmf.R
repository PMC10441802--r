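#' Control parameters for symmetric simplex matrix factorisation
#'
#' @param max_iter maximum gradient iterations per restart.
#' @param tol relative decrease of the objective below which iteration stops.
#' @param lambda L2 regularisation strength: the penalty
#'   \eqn{\lambda \|A\|_F^2} is added to the factorisation objective. Its
#'   practical role is to discourage redundant allocation columns from
#'   retaining mass, so that a solution can occupy fewer than \code{k}
#'   clusters (see \code{\link{prune_empty_clusters}}).
#' @param n_restarts number of random initialisations; the run with the best
#'   final objective is kept.
#' @param seed integer seed for the random initialisations (optional).
#' @param mass_threshold column-mass fraction below which a cluster is
#'   considered empty when pruning.
#' @return list of class \code{ssmf_control}.
#' @export
ssmf_control <- function(max_iter = 5000, tol = 1e-8, lambda = 0.01,
                         n_restarts = 5, seed = NULL, mass_threshold = 0.01) {
  stopifnot(max_iter >= 1, tol > 0, lambda >= 0, n_restarts >= 1,
            mass_threshold >= 0, mass_threshold < 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol, lambda = lambda,
                 n_restarts = as.integer(n_restarts), seed = seed,
                 mass_threshold = mass_threshold),
            class = "ssmf_control")
}

#' Symmetric simplex matrix factorisation
#'
#' Factorises an N x N consensus (posterior similarity) matrix C into an
#' N x k matrix A of cluster allocation probabilities with rows on the
#' probability simplex, by minimising the off-diagonal residual
#' \deqn{\sum_{i \ne j} (C_{ij} - (AA^\top)_{ij})^2 + \lambda \|A\|_F^2}
#' with projected gradient descent: after each gradient step every row is
#' projected back onto the simplex (Euclidean projection), and the step size
#' is chosen by backtracking line search, so the objective is non-increasing
#' across iterations. The diagonal of C is excluded because it is fixed to 1
#' by construction and carries no co-assignment information.
#'
#' The problem is non-convex; \code{n_restarts} symmetric-Dirichlet(1)
#' initialisations are run and the best final objective kept. Results are
#' deterministic given \code{control$seed}.
#'
#' @param consensus N x N consensus matrix (symmetric, unit diagonal,
#'   entries in \[0, 1\]).
#' @param k number of allocation columns (the target cluster count).
#' @param control an \code{\link{ssmf_control}} object.
#' @return N x k allocation matrix with attributes \code{objective} (final
#'   objective value), \code{objective_trace} (per-iteration objective of the
#'   winning restart), \code{converged} (logical) and \code{restarts}.
#'   A warning is raised if no restart met the convergence tolerance within
#'   \code{max_iter}; the best result is still returned.
#' @export
ssmf_factorise <- function(consensus, k, control = ssmf_control()) {
  consensus <- validate_similarity(consensus, tol = 1e-8)
  n <- nrow(consensus)
  k <- as.integer(k)
  if (k < 2 || k > n) stop("k must be between 2 and N")
  if (!inherits(control, "ssmf_control")) control <- do.call(ssmf_control, control)

  if (!is.null(control$seed)) set.seed(control$seed)
  best <- NULL
  for (r in seq_len(control$n_restarts)) {
    # symmetric Dirichlet(1) rows: normalised exponentials
    A0 <- matrix(stats::rexp(n * k), n, k)
    A0 <- A0 / rowSums(A0)
    fit <- .ssmf_pgd(consensus, A0, control$max_iter, control$tol,
                     control$lambda)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!best$converged)
    warning("SSMF did not meet the convergence tolerance within max_iter; ",
            "returning the best solution found")
  A <- best$A
  colnames(A) <- paste0("cluster_", seq_len(k))
  # defensively renormalise: projection leaves rows on the simplex but
  # floating-point sums can sit 1e-16 off
  A <- A / rowSums(A)
  attr(A, "objective") <- best$objective
  attr(A, "objective_trace") <- as.numeric(best$trace)
  attr(A, "converged") <- best$converged
  attr(A, "restarts") <- control$n_restarts
  A
}

#' Remove empty clusters from an allocation matrix
#'
#' Drops allocation columns whose total mass is at most
#' \code{mass_threshold * N} and renormalises the remaining rows. The L2
#' penalty in \code{\link{ssmf_factorise}} can empty redundant columns when
#' the consensus supports fewer clusters than requested, so the final
#' solution may have fewer clusters than \code{k}.
#'
#' @param alloc N x K allocation matrix.
#' @param mass_threshold fraction of N below which a column counts as empty;
#'   in \[0, 1).
#' @return allocation matrix with the surviving columns, carrying the
#'   attribute \code{surviving_clusters}.
#' @export
prune_empty_clusters <- function(alloc, mass_threshold = 0.01) {
  stopifnot(mass_threshold >= 0, mass_threshold < 1)
  alloc <- as_allocation(alloc)
  keep <- colSums(alloc) > mass_threshold * nrow(alloc)
  if (!any(keep)) stop("all clusters fall below the mass threshold")
  out <- alloc[, keep, drop = FALSE]
  out <- out / rowSums(out)
  attr(out, "surviving_clusters") <- sum(keep)
  out
}

#' Model-based allocation uncertainty
#'
#' The probability that an observation's assigned cluster (the argmax of its
#' allocation row) is not its true cluster: \eqn{u_i = 1 - \max_k A_{ik}}.
#' Zero for a certain (hard) allocation; at most \eqn{1 - 1/K} for a uniform
#' row. Reflects both within-model softness and across-model disagreement
#' when computed on a model-averaged allocation.
#'
#' @param alloc N x K allocation matrix.
#' @return numeric vector of length N in \[0, 1 - 1/K\].
#' @export
allocation_uncertainty <- function(alloc) {
  alloc <- as_allocation(alloc)
  1 - apply(alloc, 1, max)
}

#' Choose the number of averaged clusters
#'
#' Heuristics for picking the target cluster count of the averaged solution
#' from the input models' cluster counts: either the largest input
#' \eqn{K_m} (\code{"max_k"}), or that value plus an increment
#' (\code{"max_k_plus"}) to leave room for sub-cluster structure that only
#' some models resolve — redundant clusters are emptied downstream by
#' regularisation and pruning.
#'
#' @param input_ks integer vector of per-model cluster counts.
#' @param strategy \code{"max_k"} or \code{"max_k_plus"}.
#' @param increment added to the maximum under \code{"max_k_plus"}.
#' @return integer target cluster count.
#' @export
choose_k_bma <- function(input_ks, strategy = c("max_k", "max_k_plus"),
                         increment = 1) {
  strategy <- match.arg(strategy)
  input_ks <- as.integer(input_ks)
  if (length(input_ks) == 0L) stop("empty list of cluster counts")
  k <- max(input_ks)
  if (strategy == "max_k_plus") k <- k + as.integer(increment)
  k
}
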