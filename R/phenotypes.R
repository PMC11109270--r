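## Phenotype discovery: complete-linkage hierarchical clustering of
## participants on prepared brain features, a two-group cut, orientation of
## the clusters into accelerated/delayed labels by structural integrity,
## and Table-style domain summaries.

BRAIN_DOMAINS <- c("structure.volume", "structure.dti", "metabolism",
                   "connectivity")

#' Cluster participants on prepared brain features
#'
#' Complete-linkage hierarchical clustering on Euclidean distances between
#' participant rows, restricted to brain-domain columns (structure,
#' metabolism, connectivity): cognition and nutrients are held out so that
#' between-phenotype tests on them are not circular.
#'
#' @param prep a `prepared_features` object.
#' @param domains columns entering the distance; default the brain domains.
#' @param method linkage passed to [stats::hclust()].
#' @return an [stats::hclust] tree with participant ids as labels.
#' @export
cluster_participants <- function(prep, domains = BRAIN_DOMAINS,
                                 method = "complete") {
  stop_if(!inherits(prep, "prepared_features"), "'prep' must come from prepare_features()")
  cols <- prep$manifest$feature[prep$manifest$domain %in% domains]
  stop_if(length(cols) == 0, "no prepared columns in the requested domains")
  M <- prep$values[, cols, drop = FALSE]
  stop_if(any(is.na(M)), "prepared matrix contains NA")
  stop_if(nrow(M) < 2, "need at least 2 participants")
  stats::hclust(stats::dist(M), method = method)
}

#' Cut a linkage tree into the two top-level clusters
#'
#' Removes the final merge, i.e. cuts at k = 2.
#'
#' @param tree an [stats::hclust] tree.
#' @return unoriented integer membership (named by participant).
#' @export
cut_two <- function(tree) {
  stats::cutree(tree, k = 2)
}

#' Orient cluster labels into accelerated / delayed phenotypes
#'
#' The cluster with the higher mean over the prepared structural columns
#' (volumes and DTI tracts) is labeled `delayed`, reflecting that delayed
#' brain aging shows larger volumes and higher white-matter integrity. An
#' exact tie breaks deterministically: the larger cluster, then the cluster
#' containing the lexicographically smallest participant id, is `delayed`.
#'
#' @param membership two-group membership from [cut_two()].
#' @param prep the `prepared_features` the tree was built on.
#' @return object of class `phenotype_assignment`: a named factor with
#'   levels `accelerated`, `delayed`, plus the orientation record in
#'   `attr(, "orientation")`.
#' @export
orient_labels <- function(membership, prep) {
  stop_if(length(unique(membership)) != 2, "need exactly two clusters")
  cols <- prep$manifest$feature[prep$manifest$domain %in%
                                  c("structure.volume", "structure.dti")]
  comp <- rowMeans(prep$values[, cols, drop = FALSE])
  m1 <- mean(comp[membership == 1])
  m2 <- mean(comp[membership == 2])
  if (m1 != m2) {
    delayed_cluster <- if (m1 > m2) 1L else 2L
    rule <- "higher structure.volume+structure.dti mean"
  } else {
    sz <- table(membership)
    if (sz[1] != sz[2]) {
      delayed_cluster <- as.integer(names(which.max(sz)))
      rule <- "tie on structural mean; larger cluster"
    } else {
      delayed_cluster <- membership[[order(names(membership))[1]]]
      rule <- "tie on structural mean and size; smallest participant id"
    }
  }
  lab <- factor(ifelse(membership == delayed_cluster, "delayed", "accelerated"),
                levels = c("accelerated", "delayed"))
  names(lab) <- names(membership)
  structure(lab, class = c("phenotype_assignment", "factor"),
            orientation = list(rule = rule, delayed_cluster = delayed_cluster,
                               structural_means = c(m1, m2)))
}

#' Per-domain, per-phenotype mean summary
#'
#' One row per measure family — volumetric regions, DTI tracts, MRS
#' metabolites, whole-brain connectivity, and each network-level graph
#' metric — with the accelerated and delayed means of the prepared (scaled)
#' values, mirroring the usual two-phenotype summary layout.
#'
#' @param assignment oriented `phenotype_assignment`.
#' @param prep `prepared_features`.
#' @return data.frame with columns `domain`, `measure`, `accelerated`,
#'   `delayed`; empty measure families are omitted with a warning.
#' @export
domain_summaries <- function(assignment, prep) {
  man <- prep$manifest
  conn_cols <- function(pat) man$feature[man$domain == "connectivity" &
                                           grepl(pat, man$feature)]
  fam <- list(
    list("Brain Structure", "Volumetric Regions",
         man$feature[man$domain == "structure.volume"]),
    list("Brain Structure", "Diffusion Tensor Imaging Tracts",
         man$feature[man$domain == "structure.dti"]),
    list("Brain Metabolism", "Magnetic Resonance Spectroscopy",
         man$feature[man$domain == "metabolism"]),
    list("Functional Connectivity", "Whole Brain", conn_cols("^conn_whole_brain_")),
    list("Functional Connectivity", "Small World Propensity (network)",
         setdiff(conn_cols("_swp$"), conn_cols("^conn_whole_brain_"))),
    list("Functional Connectivity", "Strength (network)",
         setdiff(conn_cols("_strength$"), conn_cols("^conn_whole_brain_"))),
    list("Functional Connectivity", "Local efficiency (network)",
         setdiff(conn_cols("_local_eff$"), conn_cols("^conn_whole_brain_"))),
    list("Functional Connectivity", "Global efficiency (network)",
         setdiff(conn_cols("_global_eff$"), conn_cols("^conn_whole_brain_")))
  )
  rows <- lapply(fam, function(f) {
    if (length(f[[3]]) == 0) {
      warning("empty measure family omitted: ", f[[2]], call. = FALSE)
      return(NULL)
    }
    sub <- prep$values[, f[[3]], drop = FALSE]
    data.frame(domain = f[[1]], measure = f[[2]],
               accelerated = mean(sub[assignment == "accelerated", ]),
               delayed = mean(sub[assignment == "delayed", ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Discover accelerated/delayed brain-health phenotypes
#'
#' The main fitting function. Prepares the cohort's features (FWL
#' residualization against covariates, Tukey Ladder-of-Powers, `[0, 1]`
#' scaling), clusters participants on the prepared brain features with
#' complete linkage, cuts the tree into two phenotypes, orients the labels
#' by structural integrity, and compares the phenotypes on every domain:
#' Welch t-tests per feature, a brain-age contrast with per-modality
#' correlations, and the delayed-phenotype nutrient profile.
#'
#' @param cohort a `cohort_table` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param covariates covariate columns residualized out.
#' @param alpha significance level for the per-feature comparisons.
#' @param cluster_domains domains entering the clustering distance.
#' @param linkage linkage method.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param separation_perms column-permutation replicates calibrating the
#'   null silhouette envelope used by the non-separation flag.
#' @return an object of class `brain_phenotypes` with components `prep`,
#'   `tree`, `assignment`, `summary_table`, `comparisons`, `brain_age`,
#'   `nutrient_profile`, `separation` (mean silhouette width of the
#'   two-group cut), `separation_null` (95th percentile of the
#'   column-permutation null), `separated` (flag) and `call`.
#' @examples
#' g <- generate_cohort(cohort_config(n_participants = 60, seed = 3))
#' fit <- brain_phenotypes(g$cohort)
#' fit
#' @export
brain_phenotypes <- function(cohort,
                             covariates = attr(cohort, "covariates"),
                             alpha = 0.05,
                             cluster_domains = BRAIN_DOMAINS,
                             linkage = "complete",
                             var_equal = FALSE,
                             separation_perms = 20L) {
  prep <- prepare_features(cohort, covariates = covariates)
  tree <- cluster_participants(prep, domains = cluster_domains, method = linkage)
  assignment <- orient_labels(cut_two(tree), prep)

  cols <- prep$manifest$feature[prep$manifest$domain %in% cluster_domains]
  M <- prep$values[, cols, drop = FALSE]
  sil <- cluster::silhouette(as.integer(assignment), stats::dist(M))
  separation <- mean(sil[, "sil_width"])
  ## permutation null: column-wise shuffles destroy the cluster structure
  ## while keeping every marginal; the observed silhouette must beat the
  ## null's upper envelope for the phenotypes to count as separated
  null_sep <- vapply(seq_len(separation_perms), function(i) with_seed(1e6 + i, {
    Mp <- apply(M, 2, sample)
    tp <- stats::hclust(stats::dist(Mp), method = linkage)
    mp <- stats::cutree(tp, k = 2)
    mean(cluster::silhouette(mp, stats::dist(Mp))[, "sil_width"])
  }), numeric(1))
  sep_threshold <- stats::quantile(null_sep, 0.95, names = FALSE)
  separated <- separation > sep_threshold

  comparisons <- compare_all(prep, assignment,
                             domains = unique(prep$manifest$domain),
                             alpha = alpha, var_equal = var_equal)
  ba <- if (!is.null(prep$brain_age))
    brain_age_report(prep, assignment, var_equal = var_equal) else NULL
  structure(list(prep = prep, tree = tree, assignment = assignment,
                 summary_table = domain_summaries(assignment, prep),
                 comparisons = comparisons,
                 brain_age = ba,
                 nutrient_profile = nutrient_profile(comparisons),
                 separation = separation, separation_null = sep_threshold,
                 separated = separated,
                 alpha = alpha, call = match.call()),
            class = "brain_phenotypes")
}

#' @export
print.brain_phenotypes <- function(x, ...) {
  tab <- table(x$assignment)
  cat("Brain-health phenotypes (complete-linkage, two-group cut)\n")
  cat(sprintf("  accelerated: %d   delayed: %d   mean silhouette: %.3f (null q95 %.3f)%s\n",
              tab[["accelerated"]], tab[["delayed"]], x$separation,
              x$separation_null,
              if (!x$separated) "  [phenotypes not separated]" else ""))
  if (!is.null(x$brain_age))
    cat(sprintf("  brain age: accelerated %.1f vs delayed %.1f yr (gap %.1f, t = %.2f, p = %.3g)\n",
                x$brain_age$mean_accelerated, x$brain_age$mean_delayed,
                x$brain_age$difference, x$brain_age$t, x$brain_age$p))
  cat(sprintf("  %d/%d features differ at alpha = %g; %d nutrients in the delayed profile\n",
              sum(x$comparisons$significant), nrow(x$comparisons), x$alpha,
              nrow(x$nutrient_profile)))
  invisible(x)
}

#' @export
summary.brain_phenotypes <- function(object, ...) {
  x <- object
  print(x)
  cat("\nDomain means of prepared [0,1] values:\n")
  print(x$summary_table, row.names = FALSE, digits = 3)
  if (!is.null(x$brain_age)) {
    cat("\nBrain-age correlations with modality composites:\n")
    print(x$brain_age$modality_correlations, row.names = FALSE, digits = 3)
  }
  if (nrow(x$nutrient_profile)) {
    cat("\nNutrient profile of the delayed phenotype:\n")
    print(x$nutrient_profile[, c("category", "name", "feature", "t_statistic",
                                 "p_value")], row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Plot the phenotype dendrogram
#'
#' Base-graphics dendrogram of the complete-linkage tree with leaf ticks
#' colored by phenotype.
#'
#' @param x a `brain_phenotypes` fit.
#' @param ... passed to [plot.hclust()].
#' @export
plot.brain_phenotypes <- function(x, ...) {
  plot(x$tree, labels = FALSE, hang = -1,
       main = "Participant clustering on brain features",
       xlab = "", sub = "", ...)
  ord <- x$tree$order
  cols <- ifelse(x$assignment[ord] == "delayed", "#2166ac", "#b2182b")
  graphics::points(seq_along(ord), rep(0, length(ord)), pch = 15, col = cols)
  graphics::legend("topright", legend = c("delayed", "accelerated"),
                   col = c("#2166ac", "#b2182b"), pch = 15, bty = "n")
  invisible(x)
}

#' @export
residuals.brain_phenotypes <- function(object, ...) {
  object$prep$residuals
}

#' Assign new participants to a fitted phenotype
#'
#' Replays the recorded preparation lineage (covariate projection, Tukey
#' lambda, scaling bounds) on new rows and assigns each to the nearer
#' phenotype centroid in the prepared brain-feature space.
#'
#' @param object a `brain_phenotypes` fit.
#' @param newdata data.frame with the same feature and covariate columns.
#' @param ... unused.
#' @return factor of phenotype labels.
#' @export
predict.brain_phenotypes <- function(object, newdata, ...) {
  P <- replay_preparation(object$prep, newdata)
  cols <- object$prep$manifest$feature[
    object$prep$manifest$domain %in% BRAIN_DOMAINS]
  cols <- intersect(cols, colnames(P))
  cen <- rbind(accelerated = colMeans(
    object$prep$values[object$assignment == "accelerated", cols, drop = FALSE]),
    delayed = colMeans(
      object$prep$values[object$assignment == "delayed", cols, drop = FALSE]))
  d <- as.matrix(stats::dist(rbind(cen, P[, cols, drop = FALSE])))[-(1:2), 1:2, drop = FALSE]
  factor(c("accelerated", "delayed")[apply(d, 1, which.min)],
         levels = c("accelerated", "delayed"))
}

#' Export a linkage tree in Newick format
#'
#' @param tree an [stats::hclust] tree.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_dendrogram <- function(tree, file) {
  ape::write.tree(ape::as.phylo(tree), file = file)
  invisible(file)
}
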