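test_that("weighted clustering matches triangle enumeration and handles degenerate nodes", {
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  expect_equal(weighted_clustering(tri), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(weighted_clustering(star), 0)
  # 5-node weighted graph against exhaustive triple enumeration
  W <- matrix(0, 5, 5)
  W[1, 2] <- 0.9; W[1, 3] <- 0.4; W[2, 3] <- 0.7; W[3, 4] <- 0.2
  W[4, 5] <- 0.6; W[2, 5] <- 0.3
  W <- W + t(W)
  expect_equal(weighted_clustering(W), enum_clustering(W), tolerance = 1e-12)
})

test_that("path length and efficiencies match Floyd-Warshall oracles", {
  two <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(as.numeric(characteristic_path_length(two)), 2)
  K <- matrix(1, 6, 6); diag(K) <- 0
  expect_equal(as.numeric(characteristic_path_length(K)), 1)
  expect_equal(as.numeric(global_efficiency(K)), 1)
  W <- rand_wgraph(10, 0.4, seed = 31)
  expect_equal(as.numeric(characteristic_path_length(W)), fw_path_length(W),
               tolerance = 1e-9)
  W2 <- rand_wgraph(12, 0.5, seed = 32)
  expect_equal(as.numeric(global_efficiency(W2)), fw_global_efficiency(W2),
               tolerance = 1e-9)
  expect_equal(as.numeric(local_efficiency(W2)), fw_local_efficiency(W2),
               tolerance = 1e-9)
  expect_error(characteristic_path_length(matrix(0, 4, 4)), "no edges")
  # edgeless graph: efficiencies and strength are flagged zeros
  z <- matrix(0, 4, 4)
  expect_equal(as.numeric(global_efficiency(z)), 0)
  expect_true(attr(global_efficiency(z), "empty"))
  expect_equal(as.numeric(strength(z)), 0)
  expect_equal(strength(two), 0.5)
})

test_that("lattice null is a fixed point on ring lattices and conserves weight", {
  W <- ring_lattice(30, 4)
  L <- lattice_null(W)
  expect_equal(unname(L), W, tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(attr(L, "approx_degrees"))
  Wr <- rand_wgraph(20, 0.3, seed = 5)
  Lr <- lattice_null(Wr)
  expect_equal(sum(Lr), sum(Wr), tolerance = 1e-9)
  expect_equal(sort(Lr[upper.tri(Lr)]), sort(Wr[upper.tri(Wr)]),
               tolerance = 1e-12)
  # larger weights sit in bands nearer the diagonal
  band <- function(M) {
    idx <- which(upper.tri(M) & M > 0, arr.ind = TRUE)
    d <- abs(idx[, 1] - idx[, 2]); n <- nrow(M)
    data.frame(d = pmin(d, n - d), w = M[idx])
  }
  b <- band(Lr)
  expect_true(min(b$w[b$d == min(b$d)]) >= max(b$w[b$d == max(b$d)]) - 1e-12)
})

test_that("random null preserves degrees and the weight multiset exactly", {
  set.seed(77)
  A <- matrix(0, 20, 20)
  A[upper.tri(A)] <- runif(190) < 0.3
  A <- A + t(A)
  W <- A * rand_wgraph(20, 1, seed = 78)  # weights on the ER support
  W <- (W + t(W)) / 2
  R <- random_null(W, seed = 3)
  expect_equal(rowSums(R > 0), rowSums(W > 0))
  expect_equal(sort(R[upper.tri(R)]), sort(W[upper.tri(W)]), tolerance = 1e-12)
  expect_equal(sum(R), sum(W), tolerance = 1e-9)
  expect_identical(random_null(W, seed = 3), R)
  expect_false(identical(random_null(W, seed = 4), R))
})

test_that("small-world propensity hits its lattice and random fixed points", {
  s_latt <- small_world_propensity(ring_lattice(30, 4), seed = 1, n_null = 10)
  expect_lte(s_latt$delta_c, 0.05)
  expect_gte(s_latt$delta_l, 0.95)
  expect_lt(abs(s_latt$phi - (1 - sqrt(0.5))), 0.03)
  set.seed(9)
  A <- matrix(0, 30, 30)
  A[upper.tri(A)] <- runif(435) < 0.9
  A <- A + t(A)
  s_rand <- small_world_propensity(A, seed = 1, n_null = 10)
  expect_gte(s_rand$delta_c, 0.95)
  expect_lte(s_rand$delta_l, 0.05)
  expect_lt(abs(s_rand$phi - (1 - sqrt(0.5))), 0.03)
  # the phi identity holds exactly from the stored deltas
  expect_equal(s_latt$phi,
               1 - sqrt((s_latt$delta_c^2 + s_latt$delta_l^2) / 2),
               tolerance = 1e-12)
})

test_that("Watts-Strogatz networks score above both fixed points and phi is permutation-invariant", {
  set.seed(15)
  g <- igraph::sample_smallworld(1, 100, 5, 0.1)
  W <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  s <- small_world_propensity(W, seed = 2, n_null = 10)
  expect_gt(s$phi, 1 - sqrt(0.5) + 0.05)
  perm <- sample(100)
  s_p <- small_world_propensity(W[perm, perm], seed = 2, n_null = 10)
  expect_lt(abs(s$phi - s_p$phi), 0.05)  # null ensembles differ only by seed path
})

test_that("feeding the nulls back in zeroes the matching deviation", {
  W <- rand_wgraph(24, 0.25, seed = 41)
  latt <- lattice_null(W)
  s1 <- small_world_propensity(latt, seed = 6, n_null = 20)
  expect_lte(s1$delta_c, 0.05)
  rnd <- random_null(W, seed = 7)
  s2 <- small_world_propensity(rnd, seed = 6, n_null = 20)
  expect_lte(s2$delta_l, 0.05)
})

test_that("participant feature records expose 4 metrics x 8 network slots", {
  p <- bold_panel(40, 150, beta = 0.15, k = 6, seed = 33)
  mats <- build_connectivity(p, default_partition(40, 7))
  feats <- participant_network_features(mats, seed = 1, n_null = 3)
  expect_length(feats, 32)
  expect_false(attr(feats, "incomplete"))
  expect_true(all(c("conn_whole_brain_swp", "conn_visual_strength") %in%
                    names(feats)))
  # a missing network flags the record incomplete with NA features
  feats7 <- participant_network_features(mats[names(mats) != "limbic"],
                                         seed = 1, n_null = 3)
  expect_true(attr(feats7, "incomplete"))
  expect_true(all(is.na(feats7[grepl("limbic", names(feats7))])))
  expect_length(feats7, 32)
})
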