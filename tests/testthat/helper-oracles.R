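# Independent brute-force reference implementations used as oracles.
# These deliberately use exhaustive loops, not the package's code paths.

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) a[i, j] <- a[j, i] <- 1L
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

brute_degree <- function(a) {
  n <- nrow(a)
  k <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (a[i, j] == 1) k[i] <- k[i] + 1L
  k
}

brute_clustering <- function(a) {
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(a[i, ] == 1)
    k <- length(nbrs)
    if (k < 2) next
    e <- 0L
    for (u in nbrs) for (v in nbrs) if (u < v && a[u, v] == 1) e <- e + 1L
    ci[i] <- e / choose(k, 2)
  }
  ci
}

# Floyd-Warshall all-pairs shortest hop counts
brute_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

brute_local_eff_literal <- function(a) {
  n <- nrow(a)
  d <- brute_distances(a)
  e <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    e[i] <- s / n
  }
  e
}

brute_local_eff_neighborhood <- function(a) {
  n <- nrow(a)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(a[i, ] == 1)
    k <- length(nbrs)
    if (k < 2) next
    dsub <- brute_distances(a[nbrs, nbrs, drop = FALSE])
    s <- 0
    for (u in seq_len(k)) for (v in seq_len(k))
      if (u != v && is.finite(dsub[u, v])) s <- s + 1 / dsub[u, v]
    e[i] <- s / (k * (k - 1))
  }
  e
}

# permutation p-value oracle for a two-sided two-sample mean difference
perm_p_two_sample <- function(x, y, n_perm = 1e5) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pool), nx)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# permutation p-value oracle for a two-sided correlation test
perm_p_cor <- function(x, y, n_perm = 1e5) {
  obs <- abs(stats::cor(x, y))
  hits <- 0L
  for (b in seq_len(n_perm))
    if (abs(stats::cor(x, sample(y))) >= obs - 1e-12) hits <- hits + 1L
  (hits + 1) / (n_perm + 1)
}

# construct a sample of size n with exact mean m and exact SD s
sample_with_moments <- function(n, m, s) {
  x <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  m + s * x
}
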