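## Between-phenotype comparisons: per-feature t-tests, the brain-age
## contrast with modality correlations, and the delayed-phenotype nutrient
## profile.

#' Two-group t-test of the means
#'
#' Welch (unequal-variance) by default; pooled-variance Student's test via
#' `var_equal = TRUE`.
#'
#' @param xA,xB numeric samples with at least 2 observations each.
#' @param var_equal pooled variance instead of Welch.
#' @return list with `t`, `p`, `df`, `mean_A`, `mean_B`.
#' @export
two_group_t <- function(xA, xB, var_equal = FALSE) {
  stop_if(length(xA) < 2 || length(xB) < 2, "each group needs n >= 2")
  stop_if(stats::var(xA) == 0 && stats::var(xB) == 0,
          "degenerate: both groups have zero variance")
  ht <- stats::t.test(xA, xB, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_A = mean(xA), mean_B = mean(xB))
}

#' Compare phenotypes on every feature of the requested domains
#'
#' One record per feature: group means of the prepared values, t-statistic
#' (delayed relative to accelerated is reflected in the sign of
#' `mean_delayed - mean_accelerated`; the statistic is accelerated minus
#' delayed), unadjusted p, a significance flag at `alpha`, and a
#' Benjamini-Hochberg adjusted column alongside for transparency.
#'
#' @param prep a `prepared_features` object.
#' @param assignment oriented `phenotype_assignment`.
#' @param domains domain tags to compare (must be non-empty).
#' @param alpha significance level for the flag.
#' @param var_equal pooled-variance t-tests.
#' @return data.frame of class `comparison_table`, sorted by domain then p.
#' @export
compare_all <- function(prep, assignment, domains, alpha = 0.05,
                        var_equal = FALSE) {
  stop_if(missing(domains) || length(domains) == 0, "empty domain selection")
  man <- prep$manifest[prep$manifest$domain %in% domains, , drop = FALSE]
  stop_if(nrow(man) == 0, "no features in the requested domains")
  acc <- assignment == "accelerated"
  del <- assignment == "delayed"
  rec <- lapply(seq_len(nrow(man)), function(i) {
    x <- prep$values[, man$feature[i]]
    tt <- two_group_t(x[acc], x[del], var_equal = var_equal)
    data.frame(feature = man$feature[i], domain = man$domain[i],
               mean_accelerated = tt$mean_A, mean_delayed = tt$mean_B,
               t_statistic = tt$t, p_value = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$domain, out$p_value), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Brain-age contrast between phenotypes
#'
#' Group means of brain age in years, their difference (accelerated minus
#' delayed, exactly), the t-test of the contrast, and Pearson correlations
#' (with p-values) between brain age and each modality composite — the
#' unweighted mean of the prepared `[0, 1]` columns per domain (volumes,
#' tracts, metabolites, connectivity). Columns whose manifest `direction`
#' is -1 (graph metrics that run opposite to brain health) enter the
#' composite reflected as `1 - x`, so every composite points toward better
#' brain health.
#'
#' @param prep `prepared_features` carrying the raw `brain_age` column.
#' @param assignment oriented `phenotype_assignment`.
#' @param var_equal pooled-variance t-test.
#' @return list of class `brain_age_report`: `mean_accelerated`,
#'   `mean_delayed`, `difference`, `t`, `p`, `modality_correlations`
#'   (data.frame with `modality`, `r`, `p`, `degenerate`).
#' @export
brain_age_report <- function(prep, assignment, var_equal = FALSE) {
  ba <- prep$brain_age
  stop_if(is.null(ba), "no brain_age column available")
  acc <- assignment == "accelerated"
  tt <- two_group_t(ba[acc], ba[!acc], var_equal = var_equal)
  comps <- list(volumes = "structure.volume", tracts = "structure.dti",
                metabolites = "metabolism", connectivity = "connectivity")
  cors <- lapply(names(comps), function(nm) {
    sel <- prep$manifest$domain == comps[[nm]]
    cols <- prep$manifest$feature[sel]
    if (length(cols) == 0)
      return(data.frame(modality = nm, r = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    dirs <- prep$manifest$direction[sel]
    vals <- prep$values[, cols, drop = FALSE]
    vals[, dirs < 0] <- 1 - vals[, dirs < 0]
    comp <- rowMeans(vals)
    if (stats::sd(ba) == 0 || stats::sd(comp) == 0)
      return(data.frame(modality = nm, r = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    ct <- stats::cor.test(ba, comp)
    data.frame(modality = nm, r = unname(ct$estimate), p = ct$p.value,
               degenerate = FALSE)
  })
  structure(list(mean_accelerated = tt$mean_A, mean_delayed = tt$mean_B,
                 difference = tt$mean_A - tt$mean_B,
                 t = tt$t, p = tt$p,
                 modality_correlations = do.call(rbind, cors)),
            class = "brain_age_report")
}

#' @export
print.brain_age_report <- function(x, ...) {
  cat(sprintf("Brain age: accelerated %.2f yr, delayed %.2f yr, gap %.2f yr (t = %.2f, p = %.4g)\n",
              x$mean_accelerated, x$mean_delayed, x$difference, x$t, x$p))
  print(x$modality_correlations, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Nutrient profile of the delayed phenotype
#'
#' The nutrient-domain comparison records that are significant at the
#' recorded level *and* have a higher delayed than accelerated mean,
#' annotated with nutrient category and display name.
#'
#' @param records a `comparison_table` from [compare_all()].
#' @return data.frame (possibly empty) with columns `category`, `name`,
#'   `feature`, group means, `t_statistic`, `p_value`.
#' @export
nutrient_profile <- function(records) {
  nut <- records[records$domain == "nutrient", , drop = FALSE]
  prof <- nut[nut$significant & nut$mean_delayed > nut$mean_accelerated, ,
              drop = FALSE]
  cat_tbl <- nutrient_catalog()
  idx <- match(prof$feature, cat_tbl$feature)
  prof$category <- ifelse(is.na(idx), "Other", cat_tbl$category[idx])
  prof$name <- ifelse(is.na(idx), prof$feature, cat_tbl$name[idx])
  prof <- prof[order(prof$category, prof$p_value),
               c("category", "name", "feature", "mean_accelerated",
                 "mean_delayed", "t_statistic", "p_value")]
  rownames(prof) <- NULL
  prof
}
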