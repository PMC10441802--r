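# Small deterministic fixtures shared across test files.

# three well-separated spherical blobs in 2-D
make_blobs <- function(n_per = 30, d = 8, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(d, 0), c(0, d))
  labels <- rep(1:3, each = n_per)
  features <- matrix(rnorm(3 * n_per * 2, sd = 0.5), ncol = 2) +
    centers[labels, ]
  list(features = features, labels = labels)
}

# random soft allocation with Dirichlet(1) rows
random_soft_allocation <- function(n, k) {
  a <- matrix(rexp(n * k), n, k)
  a / rowSums(a)
}
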