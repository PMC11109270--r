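# Minimal prepared_features stub built from a plain matrix, for clustering
# tests that need full control of the values.
stub_prep <- function(M, domain = "structure.volume") {
  structure(list(values = M,
                 manifest = data.frame(feature = colnames(M), domain = domain,
                                       direction = 1, effect = 0),
                 participant_id = rownames(M)),
            class = "prepared_features")
}

test_that("complete-linkage tree matches brute-force merge heights", {
  set.seed(6)
  X <- matrix(rnorm(12), 6, 2,
              dimnames = list(paste0("P", 1:6), c("f1", "f2")))
  tree <- cluster_participants(stub_prep(X))
  expect_equal(sort(tree$height), sort(enum_complete_linkage_heights(X)),
               tolerance = 1e-10)
  # two participants: single merge at their Euclidean distance
  X2 <- X[1:2, ]
  t2 <- cluster_participants(stub_prep(X2))
  expect_equal(t2$height, sqrt(sum((X2[1, ] - X2[2, ])^2)))
  # duplicated rows merge at height zero
  X3 <- rbind(X, P7 = X[1, ])
  expect_equal(min(cluster_participants(stub_prep(X3))$height), 0)
  # heights are monotone nondecreasing
  expect_true(all(diff(tree$height) >= -1e-12))
})

test_that("the two-group cut recovers well-separated blobs exactly", {
  set.seed(11)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  rownames(X) <- sprintf("P%02d", 1:40)
  colnames(X) <- c("f1", "f2")
  memb <- cut_two(cluster_participants(stub_prep(X)))
  expect_equal(ari(memb, rep(1:2, each = 20)), 1)
  # n = 2 gives singleton clusters
  m2 <- cut_two(cluster_participants(stub_prep(X[1:2, ])))
  expect_equal(sort(unname(m2)), c(1, 2))
  # row permutation yields the identical partition
  perm <- sample(40)
  mp <- cut_two(cluster_participants(stub_prep(X[perm, ])))
  expect_equal(ari(mp[rownames(X)], memb), 1)
})

test_that("label orientation puts the structurally better cluster in 'delayed'", {
  set.seed(4)
  M <- rbind(matrix(runif(60, 0.3, 0.56), 10, 6),
             matrix(runif(60, 0.44, 0.7), 10, 6))
  rownames(M) <- sprintf("P%02d", 1:20)
  colnames(M) <- paste0("vol_", 1:6)
  prep <- stub_prep(M)
  memb <- setNames(rep(1:2, each = 10), rownames(M))
  lab <- orient_labels(memb, prep)
  expect_equal(as.character(lab[11:20]), rep("delayed", 10))
  # swapping the input cluster ids leaves the oriented output unchanged
  lab2 <- orient_labels(setNames(rep(2:1, each = 10), rownames(M)), prep)
  expect_identical(as.character(lab), as.character(lab2))
  expect_match(attr(lab, "orientation")$rule, "structure")
})

test_that("planted phenotypes are recovered and oriented to the truth", {
  hits <- vapply(1:8, function(s) {
    cc <- cohort_config(n_participants = 60,
                        effect_size_brain = c(volume = 1, dti = 1,
                                              metabolism = 1, connectivity = 1),
                        seed = 100 + s)
    g <- generate_cohort(cc)
    fit <- brain_phenotypes(g$cohort)
    ari(as.character(fit$assignment), g$truth$group)
  }, numeric(1))
  expect_gte(median(hits), 0.9)
})

test_that("domain summaries report per-family group means of scaled values", {
  g <- generate_cohort(cohort_config(n_participants = 50, seed = 31))
  prep <- prepare_features(g$cohort)
  lab <- factor(rep(c("accelerated", "delayed"), length.out = 50),
                levels = c("accelerated", "delayed"))
  names(lab) <- g$cohort$participant_id
  s <- domain_summaries(lab, prep)
  expect_equal(nrow(s), 8)
  vol_cols <- prep$manifest$feature[prep$manifest$domain == "structure.volume"]
  expect_equal(s$accelerated[s$measure == "Volumetric Regions"],
               mean(prep$values[lab == "accelerated", vol_cols]))
  # identical groups give equal means in every row
  lab_same <- lab; lab_same[] <- "accelerated"; lab_same[1] <- "delayed"
  lab_same[2] <- "delayed"
  s2 <- domain_summaries(lab_same, prep)
  expect_true(all(is.finite(s2$accelerated) & is.finite(s2$delayed)))
})

test_that("the fit is invariant to participant and column order", {
  g <- generate_cohort(cohort_config(n_participants = 40, seed = 53))
  fit <- brain_phenotypes(g$cohort)
  shuf <- g$cohort[sample(40), ]
  class(shuf) <- class(g$cohort)
  attr(shuf, "manifest") <- attr(g$cohort, "manifest")
  attr(shuf, "covariates") <- attr(g$cohort, "covariates")
  fit2 <- brain_phenotypes(shuf)
  ids <- g$cohort$participant_id
  expect_identical(as.character(fit$assignment[ids]),
                   as.character(fit2$assignment[ids]))
})

test_that("prediction replays lineage and matches the training assignment", {
  g <- generate_cohort(cohort_config(n_participants = 50, seed = 71))
  fit <- brain_phenotypes(g$cohort)
  pred <- predict(fit, as.data.frame(g$cohort))
  agree <- mean(as.character(pred) == as.character(fit$assignment))
  expect_gt(agree, 0.9)
})

test_that("dendrograms export to Newick with one leaf per participant", {
  g <- generate_cohort(cohort_config(n_participants = 12, seed = 5))
  fit <- brain_phenotypes(g$cohort)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(fit$tree, f)
  tr <- ape::read.tree(f)
  expect_equal(sort(tr$tip.label), sort(g$cohort$participant_id))
})
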