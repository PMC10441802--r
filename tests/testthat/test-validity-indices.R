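test_that("Calinski-Harabasz matches the sums-of-squares oracle exactly", {
  # two tight blobs around (0,0) and (10,0)
  X <- rbind(c(-0.1, 0), c(0, 0), c(0.1, 0), c(9.9, 0), c(10, 0), c(10.1, 0))
  lab <- rep(1:2, each = 3)
  expect_equal(calinski_harabasz(X, lab), ch_oracle(X, lab), tolerance = 1e-10)
  expect_equal(calinski_harabasz(X, lab), 15000, tolerance = 1e-10)
  expect_equal(calinski_harabasz(toy8, toy8_lab), ch_oracle(toy8, toy8_lab),
               tolerance = 1e-10)
})

test_that("pairwise-centroid variant matches its own literal transcription", {
  lev <- 1:2
  centres <- t(sapply(lev, function(l) colMeans(toy8[toy8_lab == l, ])))
  num <- 0
  for (k in lev) for (j in lev) if (j != k)
    num <- num + sum(toy8_lab == k) * sum((centres[j, ] - centres[k, ])^2)
  wgss <- 0
  for (l in lev) {
    pts <- toy8[toy8_lab == l, ]
    ck <- colMeans(pts)
    wgss <- wgss + sum(sweep(pts, 2, ck)^2)
  }
  expected <- (num / 1) / (wgss / 6)
  expect_equal(calinski_harabasz_pairwise(toy8, toy8_lab), expected,
               tolerance = 1e-10)
})

test_that("separated blobs outscore a random relabelling of the same points", {
  b <- make_blobs(20)
  set.seed(3)
  expect_gt(calinski_harabasz(b$features, b$labels),
            10 * calinski_harabasz(b$features, sample(b$labels)))
})

test_that("indices are invariant to relabelling and observation order", {
  b <- make_blobs(15)
  relab <- c(3L, 1L, 2L)[b$labels]
  expect_equal(calinski_harabasz(b$features, b$labels),
               calinski_harabasz(b$features, relab))
  expect_equal(s_dbw(b$features, b$labels), s_dbw(b$features, relab))
  set.seed(4)
  p <- sample(nrow(b$features))
  expect_equal(calinski_harabasz(b$features[p, ], b$labels[p]),
               calinski_harabasz(b$features, b$labels))
  expect_equal(s_dbw(b$features[p, ], b$labels[p]),
               s_dbw(b$features, b$labels))
})

test_that("S_Dbw matches the term-by-term oracle on the 8-point configuration", {
  expect_equal(s_dbw(toy8, toy8_lab), sdbw_oracle(toy8, toy8_lab),
               tolerance = 1e-10)
  # the chosen geometry exercises a non-zero density term
  expect_gt(sdbw_oracle(toy8, toy8_lab), 0.5)
})

test_that("density term vanishes for far-separated compact clusters", {
  X <- rbind(c(0, 0), c(0.2, 0), c(0, 0.2), c(100, 0), c(100.2, 0), c(100, 0.2))
  lab <- rep(1:2, each = 3)
  expect_equal(s_dbw(X, lab), sdbw_oracle(X, lab), tolerance = 1e-12)
  # with Dens = 0 the index reduces to the scatter ratio
  popnorm <- function(pts) {
    mu <- colMeans(pts)
    sqrt(sum(colMeans(sweep(pts, 2, mu)^2)^2))
  }
  scat <- mean(c(popnorm(X[1:3, ]), popnorm(X[4:6, ]))) / popnorm(X)
  expect_equal(s_dbw(X, lab), scat, tolerance = 1e-12)
})

test_that("duplicating every point leaves S_Dbw unchanged", {
  expect_equal(s_dbw(rbind(toy8, toy8), rep(toy8_lab, 2)),
               s_dbw(toy8, toy8_lab), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(calinski_harabasz(toy8, rep(1, 8)), "two non-empty")
  expect_error(s_dbw(matrix(1, 6, 2), rep(1:2, 3)), "zero dataset variance")
})

test_that("index dispatch crisp-projects soft allocations first", {
  b <- make_blobs(15)
  hard <- labels_to_allocation(b$labels, 3)
  expect_equal(compute_civi("ch", b$features, hard),
               calinski_harabasz(b$features, b$labels))
  # soften the hard allocation without moving any argmax
  soft <- hard * 0.8 + 0.2 / 3
  expect_equal(compute_civi("ch", b$features, soft),
               calinski_harabasz(b$features, b$labels))
  expect_error(compute_civi("no_such_index", b$features, hard), "unknown")
})

test_that("registry reports directions and accepts new indices", {
  expect_equal(civi_direction("ch"), "maximise")
  expect_equal(civi_direction("sdbw"), "minimise")
  register_civi("negch", function(f, l) -calinski_harabasz(f, l), "minimise")
  expect_true("negch" %in% civi_names())
})

test_that("weight normalisation matches hand arithmetic in both directions", {
  w <- normalise_weights(c(100, 300), "maximise")
  expect_equal(w$weight, c(0.25, 0.75))
  w2 <- normalise_weights(c(2, 2, 4), "minimise")
  expect_equal(w2$weight, c(0.4, 0.4, 0.2))
  w3 <- normalise_weights(rep(7, 5), "maximise")
  expect_equal(w3$weight, rep(1 / 5, 5))
})

test_that("weights sum to one and are scale-invariant (property)", {
  set.seed(5)
  for (rep in 1:20) {
    raw <- rexp(sample(2:8, 1)) + 0.01
    for (dir in c("maximise", "minimise")) {
      w <- normalise_weights(raw, dir)
      expect_equal(sum(w$weight), 1, tolerance = 1e-10)
      expect_true(all(w$weight > 0))
      w_scaled <- normalise_weights(raw * 17.3, dir)
      expect_equal(w$weight, w_scaled$weight, tolerance = 1e-12)
    }
  }
})

test_that("invalid raw scores are rejected rather than silently shifted", {
  expect_error(normalise_weights(c(-1, 2), "maximise"), "negative")
  expect_error(normalise_weights(c(0, 2), "minimise"), "strictly positive")
  expect_error(normalise_weights(c(0, 0), "maximise"), "zero")
  expect_error(normalise_weights(c(1, Inf), "maximise"), "finite")
})

test_that("CH rises and S_Dbw falls as cluster separation grows", {
  seps <- c(-0.15, -0.05, 0.1)
  ch_means <- numeric(3); sdbw_means <- numeric(3)
  for (i in seq_along(seps)) {
    ch_r <- sdbw_r <- numeric(3)
    for (r in 1:3) {
      d <- simulate_clusters(3, 60, 2, sep_val = seps[i], seed = 100 * i + r)
      ch_r[r] <- calinski_harabasz(d$features, d$labels)
      sdbw_r[r] <- s_dbw(d$features, d$labels)
    }
    ch_means[i] <- mean(ch_r); sdbw_means[i] <- mean(sdbw_r)
  }
  expect_true(all(diff(ch_means) > 0))
  expect_true(all(diff(sdbw_means) < 0))
})
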