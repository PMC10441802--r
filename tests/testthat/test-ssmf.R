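test_that("factorisation recovers a hard clustering from its own similarity", {
  truth <- rep(1:3, each = 10)
  C <- allocation_to_similarity(labels_to_allocation(truth, 3))
  A <- ssmf_factorise(C, 3, ssmf_control(seed = 1, lambda = 0))
  R <- C - tcrossprod(A)
  diag(R) <- 0
  expect_lt(max(abs(R)), 1e-6)
  expect_equal(adjusted_rand_index(crisp_labels(A), truth), 1)
  # with the default regularisation the clustering is still exact
  A2 <- ssmf_factorise(C, 3, ssmf_control(seed = 1))
  expect_equal(adjusted_rand_index(crisp_labels(A2), truth), 1)
  expect_lt(max(allocation_uncertainty(A2)), 1e-3)
})

test_that("objective is monotone non-increasing and rows stay on the simplex", {
  set.seed(31)
  sims <- lapply(1:3, function(i)
    allocation_to_similarity(random_soft_allocation(25, 3)))
  C <- consensus_matrix(sims, rep(1 / 3, 3))
  A <- ssmf_factorise(C, 3, ssmf_control(seed = 2))
  tr <- attr(A, "objective_trace")
  expect_true(all(diff(tr) <= 1e-12))
  expect_equal(rowSums(A), rep(1, 25), tolerance = 1e-8)
  expect_true(all(A >= 0))
})

test_that("an uninformative all-ones consensus collapses onto one column", {
  C <- matrix(1, 12, 12)
  A <- ssmf_factorise(C, 2, ssmf_control(seed = 1))
  cs <- sort(colSums(A))
  expect_lt(cs[1], 0.1)        # emptied column
  expect_gt(cs[2], 11.9)       # all mass in the survivor
})

test_that("two never-co-assigned points split into opposite clusters", {
  C <- diag(2)
  A <- ssmf_factorise(C, 2, ssmf_control(seed = 1))
  lab <- crisp_labels(A)
  expect_equal(sort(lab), c(1L, 2L))
  expect_gt(max(A[1, ]), 0.99)
  expect_gt(max(A[2, ]), 0.99)
})

test_that("permuting the consensus permutes the recovered clustering", {
  truth <- rep(1:3, each = 8)
  C <- allocation_to_similarity(labels_to_allocation(truth, 3))
  set.seed(32)
  p <- sample(24)
  A <- ssmf_factorise(C[p, p], 3, ssmf_control(seed = 3))
  expect_equal(adjusted_rand_index(crisp_labels(A), truth[p]), 1)
})

test_that("non-symmetric input and bad k are rejected; non-convergence warns", {
  C <- allocation_to_similarity(labels_to_allocation(rep(1:2, 5), 2))
  bad <- C; bad[1, 2] <- 0.3
  expect_error(ssmf_factorise(bad, 2), "symmetric")
  expect_error(ssmf_factorise(C, 1), "between 2 and N")
  expect_warning(ssmf_factorise(C, 2, ssmf_control(seed = 1, max_iter = 2,
                                                   n_restarts = 1)),
                 "convergence")
})

test_that("factorisation is deterministic given the seed", {
  set.seed(33)
  C <- consensus_matrix(lapply(1:2, function(i)
    allocation_to_similarity(random_soft_allocation(15, 3))), c(0.5, 0.5))
  A1 <- ssmf_factorise(C, 3, ssmf_control(seed = 7))
  A2 <- ssmf_factorise(C, 3, ssmf_control(seed = 7))
  expect_identical(A1, A2)
})

test_that("pruning removes only below-threshold columns and renormalises", {
  A <- cbind(labels_to_allocation(rep(1:2, each = 5), 2), 0)
  A <- as_allocation(A)
  P <- prune_empty_clusters(A)
  expect_equal(ncol(P), 2L)
  expect_equal(attr(P, "surviving_clusters"), 2L)
  expect_equal(rowSums(P), rep(1, 10))
  # nothing below threshold: identity
  B <- as_allocation(labels_to_allocation(rep(1:2, each = 5), 2))
  expect_equal(ncol(prune_empty_clusters(B)), 2L)
  expect_error(prune_empty_clusters(B, 0.99), "below the mass threshold")
})

test_that("a requested-but-unsupported third cluster is emptied and pruned", {
  truth <- rep(1:2, each = 15)
  C <- allocation_to_similarity(labels_to_allocation(truth, 2))
  A <- ssmf_factorise(C, 3, ssmf_control(seed = 4))
  P <- prune_empty_clusters(A)
  expect_equal(attr(P, "surviving_clusters"), 2L)
  expect_equal(adjusted_rand_index(crisp_labels(P), truth), 1)
})

test_that("uncertainty is one minus the top allocation probability", {
  expect_equal(allocation_uncertainty(matrix(c(1, 0, 0), 1)), 0)
  expect_equal(allocation_uncertainty(matrix(c(0.5, 0.3, 0.2), 1)), 0.5)
  expect_equal(allocation_uncertainty(matrix(0.25, 1, 4)), 0.75)
})

test_that("target cluster count heuristics follow the input models", {
  expect_equal(choose_k_bma(c(3, 2)), 3L)
  expect_equal(choose_k_bma(c(5, 5, 5)), 5L)
  expect_equal(choose_k_bma(c(4, 3), "max_k_plus"), 5L)
  expect_equal(choose_k_bma(c(4, 3), "max_k_plus", increment = 2), 6L)
  expect_error(choose_k_bma(integer(0)), "empty")
})
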