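test_that("the separation-to-distance map matches the closed form", {
  z <- qnorm(0.975)
  expect_equal(separation_to_distance(0.1), 2 * z * 1.1 / 0.9)
  expect_equal(separation_to_distance(0), 2 * z)
  # inverse relation: (delta - 2z)/(delta + 2z) recovers the index
  for (J in c(-0.15, -0.05, 0.1, 0.5)) {
    delta <- separation_to_distance(J)
    expect_equal((delta - 2 * z) / (delta + 2 * z), J, tolerance = 1e-12)
  }
  expect_error(separation_to_distance(1), "\\(-1, 1\\)")
})

test_that("empirical separation of 1-D Gaussian samples matches the closed form", {
  set.seed(41)
  delta <- separation_to_distance(0.1) # ~4.79 for J = 0.1
  a <- matrix(rnorm(20000), ncol = 1)
  b <- matrix(rnorm(20000, mean = delta), ncol = 1)
  expect_lt(abs(separation_index(a, b) - 0.1), 0.02)
  # fully overlapping samples score negative
  expect_lt(separation_index(a, matrix(rnorm(20000), ncol = 1)), -0.5)
  # a huge gap drives the index toward 1
  expect_gt(separation_index(a, a + 1000), 0.95)
})

test_that("separation index is symmetric in its arguments", {
  set.seed(42)
  a <- matrix(rnorm(400), ncol = 2)
  b <- matrix(rnorm(400, mean = 2), ncol = 2)
  expect_equal(separation_index(a, b), separation_index(b, a),
               tolerance = 1e-6)
  expect_error(separation_index(a[0, , drop = FALSE], b), "non-empty")
  expect_error(separation_index(a, b, alpha = 0.7), "alpha")
})

test_that("generated datasets have the requested structure and are reproducible", {
  d <- simulate_clusters(3, 500, 2, sep_val = 0.1, seed = 5)
  expect_equal(dim(d$features), c(1500L, 2L))
  expect_equal(as.vector(table(d$labels)), rep(500L, 3))
  d2 <- simulate_clusters(3, 500, 2, sep_val = 0.1, seed = 5)
  expect_identical(d$features, d2$features)
  expect_error(simulate_clusters(4, 10, 2, sep_val = 0), "n_dims")
})

test_that("all centre pairs are equidistant at the prescribed distance", {
  for (J in c(-0.15, 0.1)) {
    d <- simulate_clusters(4, 1, 5, sep_val = J, seed = 1)
    dists <- as.vector(dist(d$centers))
    expect_equal(dists, rep(separation_to_distance(J), 6), tolerance = 1e-10)
  }
})

test_that("realised separation converges to the target at large samples", {
  d <- simulate_clusters(3, 5000, 2, sep_val = 0.1, seed = 6)
  j <- separation_index(d$features[d$labels == 1, ],
                        d$features[d$labels == 2, ])
  expect_lt(abs(j - 0.1), 0.03)
  # sample means near the planted centres, covariance near identity
  for (k in 1:3) {
    pts <- d$features[d$labels == k, ]
    expect_lt(max(abs(colMeans(pts) - d$centers[k, ])), 0.1)
    expect_lt(max(abs(cov(pts) - diag(2))), 0.1)
  }
})

test_that("simulated datasets round-trip through CSV with their sidecar", {
  skip_if_not_installed("jsonlite")
  d <- simulate_clusters(3, 10, 2, sep_val = 0, seed = 7)
  f <- tempfile(fileext = ".csv")
  write_simdata(d, f)
  r <- read_simdata(f)
  expect_equal(r$features, d$features, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(r$labels, d$labels)
  expect_equal(r$spec$sep_val, 0)
})

test_that("base-clusterer accuracy is monotone in the separation index", {
  seps <- c(-0.15, -0.05, 0.1)
  for (alg in c("kmeans", "gmm", "hc_ward")) {
    m <- sapply(seq_along(seps), function(i) {
      mean(sapply(1:3, function(r) {
        d <- simulate_clusters(3, 100, 2, sep_val = seps[i],
                               seed = 7000 + 10 * i + r)
        A <- run_clusterer(alg, d$features, 3, seed = r)
        adjusted_rand_index(crisp_labels(A), d$labels)
      }))
    })
    expect_true(all(diff(m) > 0), info = alg)
  }
})
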