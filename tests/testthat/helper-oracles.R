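# Independent brute-force oracles. None of these call package code or
# igraph: they exist to cross-check the graph, regression and clustering
# routines by direct enumeration.

# All-pairs shortest paths by Floyd-Warshall on edge lengths 1/weight.
fw_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

fw_path_length <- function(W) {
  D <- fw_distances(W)
  d <- D[row(D) != col(D)]
  mean(d[is.finite(d)])
}

fw_global_efficiency <- function(W) {
  D <- fw_distances(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(W)
  sum(inv) / (n * (n - 1))
}

fw_local_efficiency <- function(W) {
  n <- nrow(W)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    fw_global_efficiency(W[nb, nb, drop = FALSE])
  }, numeric(1)))
}

# Onnela clustering by exhaustive enumeration of ordered node triples.
enum_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(0)
  Wn <- W / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

# Agglomerative complete linkage by direct max-distance enumeration;
# returns the sorted merge heights.
enum_complete_linkage_heights <- function(X) {
  clusters <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_len(a - 1)) {
      h <- max(D[clusters[[a]], clusters[[b]]])
      if (h < best[1]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1])
    clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Least-squares residuals via the normal equations.
ne_residuals <- function(y, M) {
  beta <- solve(t(M) %*% M, t(M) %*% y)
  as.numeric(y - M %*% beta)
}

# Welch t and Satterthwaite df by the closed-form expressions.
welch_oracle <- function(xA, xB) {
  vA <- var(xA) / length(xA)
  vB <- var(xB) / length(xB)
  t <- (mean(xA) - mean(xB)) / sqrt(vA + vB)
  df <- (vA + vB)^2 / (vA^2 / (length(xA) - 1) + vB^2 / (length(xB) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# Seeded Erdos-Renyi weighted graph (symmetric, zero diagonal).
rand_wgraph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- (runif(sum(up)) < p) * runif(sum(up), 0.1, 1)
  A + t(A)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
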