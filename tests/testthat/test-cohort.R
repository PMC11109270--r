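test_that("same config and seed reproduce the cohort exactly", {
  cc <- cohort_config(n_participants = 30, seed = 42)
  g1 <- generate_cohort(cc)
  g2 <- generate_cohort(cc)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$group, g2$truth$group)
  g3 <- generate_cohort(cohort_config(n_participants = 30, seed = 43))
  expect_false(identical(g1$cohort$brain_age, g3$cohort$brain_age))
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(group_fraction = 1), "group_fraction")
  expect_error(cohort_config(brain_age_means = c(NA, 60)), "brain_age_means")
  expect_error(cohort_config(effect_size_brain = c(volume = Inf, dti = 1,
                                                   metabolism = 1,
                                                   connectivity = 1)),
               "effect_size_brain")
  expect_error(cohort_config(n_timepoints = 3), "n_timepoints")
})

test_that("planted brain-age gap and feature effects are recovered", {
  g <- generate_cohort(cohort_config(n_participants = 100, seed = 7))
  ba <- tapply(g$cohort$brain_age, g$truth$group, mean)
  # gap of 5.4 years within sampling error (SE of the gap = 2 yr at n=100)
  expect_lt(abs((ba[["accelerated"]] - ba[["delayed"]]) - 5.4), 6)
  # every Gaussian feature mean difference within 3 standard errors
  man <- attr(g$cohort, "manifest")
  del <- g$truth$group == "delayed"
  se <- sqrt(1 / sum(del) + 1 / sum(!del))
  diffs <- vapply(man$feature, function(f)
    mean(g$cohort[[f]][del]) - mean(g$cohort[[f]][!del]), numeric(1))
  expect_true(all(abs(diffs - man$effect) < 3 * se))
})

test_that("zero planted effects give significant t-tests at the alpha rate only", {
  pvals <- unlist(lapply(1:5, function(s) {
    cc <- cohort_config(n_participants = 80,
                        effect_size_brain = c(volume = 0, dti = 0,
                                              metabolism = 0, connectivity = 0),
                        effect_size_cognitive = 0,
                        nutrient_panel = setNames(rep(0, 29),
                                                  names(default_nutrient_panel())),
                        seed = s)
    g <- generate_cohort(cc)
    man <- attr(g$cohort, "manifest")
    del <- g$truth$group == "delayed"
    vapply(man$feature, function(f)
      t.test(g$cohort[[f]][del], g$cohort[[f]][!del])$p.value, numeric(1))
  }))
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("covariates are independent of the planted group labels", {
  rs <- vapply(1:20, function(s) {
    g <- generate_cohort(cohort_config(n_participants = 60, seed = s))
    grp <- as.numeric(g$truth$group == "delayed")
    max(abs(cor(grp, g$cohort$age)), abs(cor(grp, g$cohort$education)),
        abs(cor(grp, g$cohort$bmi)))
  }, numeric(1))
  # max |r| over three covariates stays within the null envelope at n=60
  expect_lt(median(rs), 0.25)
})

test_that("reverse-scored cognitive features carry a negated planted effect", {
  man <- attr(generate_cohort(cohort_config(seed = 1))$cohort, "manifest")
  rev <- man[man$feature %in% c("dkefs_trails_5", "dkefs_trails_errors"), ]
  expect_true(all(rev$effect < 0))
  expect_true(all(rev$direction == -1))
  other <- man[man$domain == "cognition" &
                 !man$feature %in% rev$feature, ]
  expect_true(all(other$effect > 0))
})

test_that("manifest counts follow the configured arithmetic", {
  cc <- cohort_config()
  man <- attr(generate_cohort(cc)$cohort, "manifest")
  expect_equal(sum(man$domain == "structure.volume"), 68)
  expect_equal(sum(man$domain == "structure.dti"), 34)
  expect_equal(sum(man$domain == "metabolism"), 3)
  expect_equal(sum(man$domain == "connectivity"), 32)
  expect_equal(sum(man$domain == "cognition"), 15)
  # total brain features derive from the config, not a hard-coded constant
  cc2 <- cohort_config(n_volumes = 10, n_tracts = 5)
  man2 <- attr(generate_cohort(cc2)$cohort, "manifest")
  expect_equal(sum(man2$domain %in% c("structure.volume", "structure.dti",
                                      "metabolism", "connectivity")),
               10 + 5 + 3 + 32)
})

test_that("cohort round-trips through delimited text", {
  g <- generate_cohort(cohort_config(n_participants = 12, seed = 3))
  d <- withr::local_tempdir()
  write_cohort(g$cohort, d)
  back <- read_cohort(d)
  expect_equal(as.data.frame(back)$brain_age, g$cohort$brain_age, tolerance = 1e-12)
  expect_equal(attr(back, "manifest")$feature, attr(g$cohort, "manifest")$feature)
})

test_that("bold panels are reproducible and respect the independence limit", {
  p1 <- bold_panel(20, 50, beta = 0.2, k = 4, seed = 9)
  p2 <- bold_panel(20, 50, beta = 0.2, k = 4, seed = 9)
  expect_identical(p1, p2)
  expect_error(bold_panel(20, 3, beta = 0.2), "n - 3")
  # independent noise: off-diagonal sample correlations centered at 0
  p0 <- bold_panel(30, 400, beta = 0.2, k = 4, edge_cor = 0, seed = 5)
  r <- cor(t(p0))
  expect_lt(abs(mean(r[upper.tri(r)])), 0.02)
})

test_that("delayed-group panels yield higher small-world propensity than accelerated", {
  cc <- cohort_config(n_participants = 8, n_nodes = 60, n_timepoints = 210,
                      ws_k = 8, seed = 21)
  g <- generate_cohort(cc)
  phi_for <- function(beta, seed) {
    p <- bold_panel(60, 210, beta = beta, k = 8, seed = seed)
    W <- build_connectivity(p, default_partition(60))$whole_brain
    small_world_propensity(unclass(W), seed = seed, n_null = 5)$phi
  }
  del <- vapply(1:6, function(s) phi_for(cc$ws_beta[["delayed"]], s), numeric(1))
  acc <- vapply(1:6, function(s) phi_for(cc$ws_beta[["accelerated"]], 100 + s), numeric(1))
  expect_gt(mean(del), mean(acc))
  # and the truth-driven wrapper picks the group parameter
  pan <- generate_timeseries(g$truth, cc, participant = 1)
  expect_equal(dim(pan), c(60, 210))
  expect_identical(pan, generate_timeseries(g$truth, cc, participant = 1))
})
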