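# Independent term-by-term transcriptions of the index definitions, written
# as explicit loops so they share no code with the implementation.

ch_oracle <- function(X, lab) {
  lev <- sort(unique(lab))
  K <- length(lev); N <- nrow(X)
  grand <- colMeans(X)
  bgss <- 0; wgss <- 0
  for (l in lev) {
    pts <- X[lab == l, , drop = FALSE]
    ck <- colMeans(pts)
    bgss <- bgss + nrow(pts) * sum((ck - grand)^2)
    for (i in seq_len(nrow(pts))) wgss <- wgss + sum((pts[i, ] - ck)^2)
  }
  (bgss / (K - 1)) / (wgss / (N - K))
}

sdbw_oracle <- function(X, lab) {
  lev <- sort(unique(lab))
  K <- length(lev)
  varnorm <- function(pts) {
    mu <- colMeans(pts)
    v <- numeric(ncol(pts))
    for (j in seq_len(ncol(pts))) v[j] <- mean((pts[, j] - mu[j])^2)
    sqrt(sum(v^2))
  }
  sig_k <- sapply(lev, function(l) varnorm(X[lab == l, , drop = FALSE]))
  scat <- mean(sig_k) / varnorm(X)
  tau <- mean(sig_k)
  f <- function(x, u) as.numeric(sqrt(sum((x - u)^2)) <= tau)
  centres <- t(sapply(lev, function(l) colMeans(X[lab == l, , drop = FALSE])))
  dens <- 0
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j == k) next
    ukj <- (centres[k, ] + centres[j, ]) / 2
    un <- X[lab %in% c(lev[k], lev[j]), , drop = FALSE]
    num <- sum(apply(un, 1, f, u = ukj))
    den <- max(sum(apply(X[lab == lev[k], , drop = FALSE], 1, f,
                         u = centres[k, ])),
               sum(apply(X[lab == lev[j], , drop = FALSE], 1, f,
                         u = centres[j, ])))
    if (den > 0) dens <- dens + num / den
  }
  scat + dens / (K * (K - 1))
}

# 8-point 2-cluster configuration with a non-trivial density term
toy8 <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0),
              c(2.5, 0.2), c(3.5, 0.2), c(4.5, 0.2), c(5.5, 0.2))
toy8_lab <- rep(1:2, each = 4)
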