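## Weighted graph metrics: Onnela clustering, shortest-path statistics, the
## lattice and random null models, and small-world propensity
##   phi = 1 - sqrt((Delta_C^2 + Delta_L^2) / 2),
##   Delta_C = (C_latt - C_obs) / (C_latt - C_rand),
##   Delta_L = (L_obs - L_rand) / (L_latt - L_rand),
## with both deviations clipped to [0, 1].

#' Mean Onnela weighted clustering coefficient
#'
#' Per-node geometric-mean triangle intensity with weights normalized by the
#' matrix maximum: `C_i = sum_{jk} (w~_ij w~_ik w~_jk)^(1/3) / (k_i (k_i - 1))`
#' where `k_i` is the binary degree. Nodes of degree below 2 contribute 0.
#'
#' @param W symmetric non-negative weighted adjacency with zero diagonal.
#' @return scalar in `[0, 1]` for weights in `[0, 1]`.
#' @export
weighted_clustering <- function(W) {
  W <- check_adjacency(W)
  mx <- max(W)
  if (mx == 0) return(0)
  Wn <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  num <- diag(Wn %*% Wn %*% Wn)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

## All-pairs shortest-path distances with edge length a decreasing function
## of weight ("inv" = 1/w, "neglog" = -log(w), requiring weights <= 1).
shortest_paths_matrix <- function(W, length_map = c("inv", "neglog")) {
  length_map <- match.arg(length_map)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wts <- igraph::E(g)$weight
  len <- if (length_map == "inv") 1 / wts else {
    stop_if(any(wts > 1), "'neglog' lengths need weights <= 1")
    -log(wts)
  }
  igraph::distances(g, weights = len, algorithm = "dijkstra")
}

#' Characteristic path length of a weighted graph
#'
#' Mean shortest-path distance over ordered reachable pairs, with edge
#' length the reciprocal of the connection weight (configurable to
#' `-log(w)`). Unreachable pairs are excluded from the mean and flagged via
#' the `disconnected` attribute, since thresholded connectivity graphs can
#' fragment.
#'
#' @param W symmetric non-negative weighted adjacency, zero diagonal.
#' @param length_map `"inv"` (default) or `"neglog"`.
#' @return scalar `L`; attribute `disconnected` is `TRUE` when any pair was
#'   unreachable.
#' @export
characteristic_path_length <- function(W, length_map = "inv") {
  W <- check_adjacency(W)
  stop_if(all(W == 0), "graph has no edges: path length undefined")
  D <- shortest_paths_matrix(W, length_map)
  d <- D[row(D) != col(D)]
  reach <- is.finite(d)
  structure(mean(d[reach]), disconnected = any(!reach))
}

#' Global, local efficiency and mean strength of a weighted graph
#'
#' Global efficiency is the mean over ordered node pairs of the inverse
#' shortest-path distance (unreachable pairs contribute 0); local efficiency
#' is the mean over nodes of the global efficiency of each node's
#' neighborhood subgraph (degree < 2 contributes 0); strength is the mean
#' over nodes of summed incident weights. An edgeless graph yields 0 for all
#' three, flagged via `attr(, "empty")`.
#'
#' @param W symmetric non-negative weighted adjacency, zero diagonal.
#' @param length_map edge-length mapping, see [characteristic_path_length()].
#' @return scalar value.
#' @export
global_efficiency <- function(W, length_map = "inv") {
  W <- check_adjacency(W)
  if (all(W == 0)) return(structure(0, empty = TRUE))
  D <- shortest_paths_matrix(W, length_map)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(W)
  sum(inv) / (n * (n - 1))
}

#' @rdname global_efficiency
#' @export
local_efficiency <- function(W, length_map = "inv") {
  W <- check_adjacency(W)
  if (all(W == 0)) return(structure(0, empty = TRUE))
  n <- nrow(W)
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    as.numeric(global_efficiency(W[nb, nb, drop = FALSE], length_map))
  }, numeric(1))
  mean(eff)
}

#' @rdname global_efficiency
#' @export
strength <- function(W) {
  W <- check_adjacency(W)
  if (all(W == 0)) return(structure(0, empty = TRUE))
  mean(rowSums(W))
}

## ----- null models -------------------------------------------------------

edge_list <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  cbind(idx, w = W[idx])
}

#' Lattice null model
#'
#' Rebuilds the graph as a ring lattice: the same number of edges and the
#' identical weight multiset, placed band-by-band at increasing circular
#' distance from the diagonal with the largest weights in the nearest band.
#' A ring lattice with uniform weights is a fixed point of this
#' construction. The binary degree sequence is preserved only up to the
#' band structure; when it changes, the result carries
#' `attr(, "approx_degrees") = TRUE`.
#'
#' @param W symmetric non-negative weighted adjacency, zero diagonal.
#' @param seed unused (the construction is deterministic); kept for symmetry
#'   with [random_null()].
#' @return lattice-null weighted adjacency.
#' @export
lattice_null <- function(W, seed = NULL) {
  W <- check_adjacency(W)
  n <- nrow(W)
  ew <- sort(W[upper.tri(W)][W[upper.tri(W)] > 0], decreasing = TRUE)
  m <- length(ew)
  out <- matrix(0, n, n)
  if (m == 0) return(out)
  placed <- 0L
  for (d in seq_len(n %/% 2)) {
    ## circular band |i - j| = d (mod n)
    i <- seq_len(if (2 * d == n) n %/% 2 else n)
    j <- ((i + d - 1L) %% n) + 1L
    cap <- length(i)
    take <- min(cap, m - placed)
    if (take == 0) break
    sel <- seq_len(take)
    wsel <- ew[placed + sel]
    out[cbind(i[sel], j[sel])] <- wsel
    out[cbind(j[sel], i[sel])] <- wsel
    placed <- placed + take
  }
  dimnames(out) <- dimnames(W)
  deg_in <- sort(rowSums(W > 0))
  deg_out <- sort(rowSums(out > 0))
  structure(out, approx_degrees = !identical(deg_in, deg_out))
}

#' Random null model (degree-preserving rewiring)
#'
#' Maslov-Sneppen edge swaps on the binary structure (each node's degree is
#' preserved exactly), followed by a uniform reshuffle of the weight
#' multiset over the rewired edges. Deterministic given `seed`.
#'
#' @param W symmetric non-negative weighted adjacency, zero diagonal.
#' @param seed integer seed.
#' @param n_swaps swap attempts; default `10 *` the edge count.
#' @return randomized weighted adjacency with the same degree sequence and
#'   weight multiset.
#' @export
random_null <- function(W, seed = 1L, n_swaps = NULL) {
  W <- check_adjacency(W)
  n <- nrow(W)
  el <- edge_list(W)
  m <- nrow(el)
  if (m < 2) return(W)
  if (is.null(n_swaps)) n_swaps <- 10L * m
  with_seed(seed, {
    E <- el[, 1:2, drop = FALSE]
    A <- W > 0
    e1s <- sample.int(m, n_swaps, replace = TRUE)
    e2s <- sample.int(m, n_swaps, replace = TRUE)
    flip <- stats::runif(n_swaps) < 0.5
    for (t in seq_len(n_swaps)) {
      i1 <- e1s[t]; i2 <- e2s[t]
      if (i1 == i2) next
      a <- E[i1, 1L]; b <- E[i1, 2L]
      c <- E[i2, 1L]; d <- E[i2, 2L]
      if (flip[t]) { tmp <- c; c <- d; d <- tmp }
      ## propose (a,d) and (c,b)
      if (a == d || c == b) next
      if (A[a, d] || A[c, b]) next
      A[a, b] <- A[b, a] <- FALSE
      A[c, d] <- A[d, c] <- FALSE
      A[a, d] <- A[d, a] <- TRUE
      A[c, b] <- A[b, c] <- TRUE
      E[i1, ] <- c(min(a, d), max(a, d))
      E[i2, ] <- c(min(c, b), max(c, b))
    }
    out <- matrix(0, n, n)
    wshuf <- sample(el[, 3L])
    out[E] <- wshuf
    out[E[, 2:1, drop = FALSE]] <- wshuf
    dimnames(out) <- dimnames(W)
    out
  })
}

## ----- small-world propensity -------------------------------------------

#' Small-world propensity of a weighted network
#'
#' Quantifies how closely the network balances lattice-like clustering and
#' random-like short paths: `phi = 1 - sqrt((Delta_C^2 + Delta_L^2)/2)`,
#' where `Delta_C = (C_latt - C_obs)/(C_latt - C_rand)` and
#' `Delta_L = (L_obs - L_rand)/(L_latt - L_rand)` are the fractional
#' deviations of the observed clustering coefficient and characteristic
#' path length from lattice and random null networks built with the same
#' number of nodes, edge weights and (for the random null, exactly) the
#' same degree sequence. Both deviations are clipped to `[0, 1]`; a
#' degenerate null spread (numerator scale exceeding a near-zero
#' denominator) defines the deviation as 0 and sets a flag.
#'
#' @param W symmetric non-negative weighted adjacency, zero diagonal.
#' @param seed integer seed for the null ensembles.
#' @param n_null number of seeded random-null replicates averaged for
#'   `C_rand`/`L_rand`.
#' @param length_map edge-length mapping for path lengths.
#' @return an object of class `swp` with fields `phi`, `delta_c`,
#'   `delta_l`, the six constituent `C`/`L` values, and `clipped` /
#'   `degenerate` flags.
#' @examples
#' W <- ring_lattice(30, 4)
#' small_world_propensity(W, seed = 1)$phi  # near 1 - sqrt(1/2)
#' @export
small_world_propensity <- function(W, seed = 1L, n_null = 10L,
                                   length_map = "inv") {
  W <- check_adjacency(W)
  stop_if(all(W == 0), "graph has no edges: small-world propensity undefined")
  n_null <- check_count(n_null, "n_null")
  c_obs <- weighted_clustering(W)
  l_obs <- as.numeric(characteristic_path_length(W, length_map))

  latt <- lattice_null(W)
  c_latt <- weighted_clustering(latt)
  l_latt <- as.numeric(characteristic_path_length(latt, length_map))

  rn <- lapply(seq_len(n_null), function(k) random_null(W, seed = derive_seed(seed, k)))
  c_rand <- mean(vapply(rn, weighted_clustering, numeric(1)))
  l_rand <- mean(vapply(rn, function(g)
    as.numeric(characteristic_path_length(g, length_map)), numeric(1)))

  ratio01 <- function(num, den) {
    if (abs(den) < 1e-12) return(list(v = 0, clip = FALSE, degen = TRUE))
    v <- num / den
    list(v = min(max(v, 0), 1), clip = v < 0 || v > 1, degen = FALSE)
  }
  dc <- ratio01(c_latt - c_obs, c_latt - c_rand)
  dl <- ratio01(l_obs - l_rand, l_latt - l_rand)
  phi <- 1 - sqrt((dc$v^2 + dl$v^2) / 2)
  structure(list(phi = phi, delta_c = dc$v, delta_l = dl$v,
                 c_obs = c_obs, c_latt = c_latt, c_rand = c_rand,
                 l_obs = l_obs, l_latt = l_latt, l_rand = l_rand,
                 clipped = c(delta_c = dc$clip, delta_l = dl$clip),
                 degenerate = c(delta_c = dc$degen, delta_l = dl$degen),
                 n_null = n_null),
            class = "swp")
}

#' @export
print.swp <- function(x, ...) {
  cat(sprintf("Small-world propensity: phi = %.4f (Delta_C = %.3f, Delta_L = %.3f)\n",
              x$phi, x$delta_c, x$delta_l))
  cat(sprintf("  C: obs %.4f | lattice %.4f | random %.4f\n",
              x$c_obs, x$c_latt, x$c_rand))
  cat(sprintf("  L: obs %.4f | lattice %.4f | random %.4f  (%d null reps)\n",
              x$l_obs, x$l_latt, x$l_rand, x$n_null))
  if (any(x$clipped)) cat("  note: deviation(s) clipped to [0,1]:",
                          paste(names(x$clipped)[x$clipped], collapse = ", "), "\n")
  invisible(x)
}

#' Ring-lattice weighted adjacency
#'
#' Each node is connected to its `k/2` nearest neighbors on each side of a
#' ring, with constant weight.
#'
#' @param n nodes; `k` even total degree; `weight` edge weight.
#' @param k even total degree.
#' @param weight constant edge weight.
#' @return weighted adjacency matrix.
#' @export
ring_lattice <- function(n, k, weight = 1) {
  stop_if(k %% 2 != 0 || k >= n, "'k' must be even and below 'n'")
  W <- matrix(0, n, n)
  for (d in seq_len(k %/% 2)) {
    i <- seq_len(n)
    j <- ((i + d - 1L) %% n) + 1L
    W[cbind(i, j)] <- weight
    W[cbind(j, i)] <- weight
  }
  W
}

#' Full metric set for one network
#'
#' @param W a `connectivity` matrix (or plain weighted adjacency).
#' @param seed,n_null passed to [small_world_propensity()].
#' @return a `network_metrics` list: `global_efficiency`,
#'   `local_efficiency`, `strength`, `swp` and the network label.
#' @export
network_metric_set <- function(W, seed = 1L, n_null = 10L) {
  lbl <- attr(W, "network")
  W <- unclass(W)
  attr(W, "empty") <- attr(W, "provenance") <- NULL
  structure(list(global_efficiency = as.numeric(global_efficiency(W)),
                 local_efficiency = as.numeric(local_efficiency(W)),
                 strength = as.numeric(strength(W)),
                 swp = if (all(W == 0)) NULL else
                   small_world_propensity(W, seed = seed, n_null = n_null),
                 network_label = if (is.null(lbl)) NA_character_ else lbl),
            class = "network_metrics")
}

#' Per-participant network feature record
#'
#' Flattens four graph metrics over the expected network slots (seven
#' intrinsic networks plus whole brain by default) into a stable named
#' vector of `4 x`(number of slots) features.
#'
#' @param matrices named list of `connectivity` matrices, e.g. from
#'   [build_connectivity()].
#' @param expected character vector of required network slots.
#' @param seed,n_null passed to [small_world_propensity()].
#' @return named numeric vector (`conn_<network>_<metric>`); if any expected
#'   slot is missing the record carries `attr(, "incomplete") = TRUE` with
#'   `NA` features for the missing slots.
#' @export
participant_network_features <- function(matrices,
                                         expected = c(network_names(7L), "whole_brain"),
                                         seed = 1L, n_null = 10L) {
  mets <- connectivity_metrics()
  feats <- unlist(lapply(seq_along(expected), function(i) {
    nw <- expected[i]
    nm <- paste("conn", nw, mets, sep = "_")
    if (!nw %in% names(matrices))
      return(stats::setNames(rep(NA_real_, 4L), nm))
    ms <- network_metric_set(matrices[[nw]], seed = derive_seed(seed, i),
                             n_null = n_null)
    stats::setNames(c(ms$global_efficiency, ms$local_efficiency,
                      if (is.null(ms$swp)) NA_real_ else ms$swp$phi,
                      ms$strength), nm)
  }))
  structure(feats, incomplete = !all(expected %in% names(matrices)))
}
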