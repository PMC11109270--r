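## Synthetic cohort generator: a two-phenotype elderly cohort with planted
## group structure across every modality the phenotyping pipeline consumes.

#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter object consumed by [generate_cohort()] and
#' [generate_timeseries()]. Defaults emulate a cross-sectional study of 100
#' community-dwelling adults aged 65-75 with 68 regional gray-matter volumes,
#' 34 white-matter FA tracts, 3 MRS metabolite concentrations, 32
#' functional-connectivity features (4 graph metrics on 7 intrinsic networks
#' plus whole brain over a 200-node parcellation, 210 BOLD time points), 15
#' cognitive scores (two reverse-scored reaction-time/error measures), a
#' 29-analyte blood nutrient panel of which 13 differ between phenotypes,
#' covariates (age, sex, education, income, BMI) independent of phenotype,
#' and a per-group brain-age gap.
#'
#' Planted standardized mean differences (delayed minus accelerated, in
#' within-group SD units) default to 0.8 for volumes, 1.0 for DTI, 0.4 for
#' metabolites and 0.8 for connectivity; network strength and local/global
#' efficiency are planted with reversed sign (accelerated higher) while
#' small-world propensity and all whole-brain features favor the delayed
#' group. The brain-age SD of 10 years makes a 5.4-year group gap carry a
#' t-statistic near 2.7 at n = 100.
#'
#' @param n_participants cohort size.
#' @param group_fraction fraction of participants in the delayed group,
#'   strictly between 0 and 1.
#' @param n_volumes,n_tracts,n_metabolites,n_cognitive feature counts per
#'   modality.
#' @param n_nodes parcellation size for simulated BOLD panels.
#' @param n_networks number of intrinsic connectivity networks (whole brain
#'   is always added as an eighth slot).
#' @param n_timepoints BOLD time points per panel; must be at least 4 so the
#'   Fisher-Z standard deviation 1/sqrt(n - 3) is defined.
#' @param reverse_scored integer indices (within the cognitive block) of
#'   reverse-scored tests, generated with negated effect direction.
#' @param effect_size_brain named vector of planted d per brain domain
#'   (volume, dti, metabolism, connectivity).
#' @param effect_size_cognitive planted d for cognitive scores.
#' @param nutrient_panel named vector of planted d per nutrient; the default
#'   plants d = 0.8 on the 13-nutrient delayed profile (vaccenic and gondoic
#'   acid, ALA, EPA, docosadienoic/eicosadienoic/lignoceric acid, cis/trans
#'   lutein, zeaxanthin, alpha/gamma tocopherol, choline) and d = 0 on 16
#'   non-differing analytes.
#' @param brain_age_means group means in years, `c(accelerated, delayed)`.
#' @param brain_age_sd within-group brain-age SD in years.
#' @param ws_beta Watts-Strogatz rewiring probability per group for
#'   simulated BOLD panels; the delayed group's lower rewiring yields higher
#'   small-world propensity.
#' @param ws_k even neighborhood size of the ring substrate.
#' @param edge_cor target correlation of connected node pairs in simulated
#'   panels.
#' @param covariate_spec list of `c(mean, sd)` (or `c(lo, hi)` for uniform
#'   age) controlling covariate distributions.
#' @param seed integer random seed; identical config + seed gives identical
#'   output.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()], [generate_timeseries()]
#' @export
cohort_config <- function(n_participants = 100L,
                          group_fraction = 0.5,
                          n_volumes = 68L,
                          n_tracts = 34L,
                          n_metabolites = 3L,
                          n_nodes = 200L,
                          n_networks = 7L,
                          n_timepoints = 210L,
                          n_cognitive = 15L,
                          reverse_scored = c(12L, 13L),
                          effect_size_brain = c(volume = 0.8, dti = 1.0,
                                                metabolism = 0.4,
                                                connectivity = 0.8),
                          effect_size_cognitive = 0.4,
                          nutrient_panel = default_nutrient_panel(),
                          brain_age_means = c(accelerated = 65.1, delayed = 59.7),
                          brain_age_sd = 10,
                          ws_beta = c(accelerated = 0.9, delayed = 0.1),
                          ws_k = 10L,
                          edge_cor = 0.5,
                          covariate_spec = list(age = c(65, 75),
                                                education = c(16, 2.5),
                                                income = c(6, 2),
                                                bmi = c(27.5, 4)),
                          seed = 1L) {
  cfg <- list(
    n_participants = check_count(n_participants, "n_participants"),
    group_fraction = check_scalar(group_fraction, "group_fraction"),
    n_volumes = check_count(n_volumes, "n_volumes"),
    n_tracts = check_count(n_tracts, "n_tracts"),
    n_metabolites = check_count(n_metabolites, "n_metabolites"),
    n_nodes = check_count(n_nodes, "n_nodes", min = 4L),
    n_networks = check_count(n_networks, "n_networks"),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 4L),
    n_cognitive = check_count(n_cognitive, "n_cognitive"),
    reverse_scored = as.integer(reverse_scored),
    effect_size_brain = effect_size_brain,
    effect_size_cognitive = check_scalar(effect_size_cognitive, "effect_size_cognitive"),
    nutrient_panel = nutrient_panel,
    brain_age_means = brain_age_means,
    brain_age_sd = check_scalar(brain_age_sd, "brain_age_sd", lo = 0),
    ws_beta = ws_beta,
    ws_k = check_count(ws_k, "ws_k", min = 2L),
    edge_cor = check_scalar(edge_cor, "edge_cor", lo = 0, hi = 0.99),
    covariate_spec = covariate_spec,
    seed = check_count(seed, "seed", min = 0L)
  )
  stop_if(cfg$group_fraction <= 0 || cfg$group_fraction >= 1,
          "'group_fraction' must lie strictly between 0 and 1")
  stop_if(any(!is.finite(cfg$effect_size_brain)),
          "'effect_size_brain' contains non-finite values")
  req <- c("volume", "dti", "metabolism", "connectivity")
  stop_if(!all(req %in% names(cfg$effect_size_brain)),
          "'effect_size_brain' must name volume, dti, metabolism, connectivity")
  stop_if(any(!is.finite(cfg$nutrient_panel)) || is.null(names(cfg$nutrient_panel)),
          "'nutrient_panel' must be a named finite vector")
  stop_if(any(!is.finite(cfg$brain_age_means)) || length(cfg$brain_age_means) != 2L,
          "'brain_age_means' must be two finite group means")
  stop_if(any(cfg$reverse_scored < 1L | cfg$reverse_scored > cfg$n_cognitive),
          "'reverse_scored' indices must lie within the cognitive block")
  class(cfg) <- "cohort_config"
  cfg
}

#' Default nutrient biomarker panel with planted effects
#'
#' The 13 nutrients of the delayed-aging profile at d = 0.8 plus 16 analytes
#' planted at d = 0 (vitamins A/B2/B6/B12/D, lycopene, carotene, the
#' C10:0-C22:0 saturated fatty acids, C18:4n-3 and C22:4n-6).
#'
#' @return named numeric vector of planted standardized mean differences.
#' @export
default_nutrient_panel <- function() {
  hits <- c("c18_1n7", "c20_1n9", "c18_3n3", "c20_5n3", "c22_2n6", "c20_2n6",
            "c24_0", "cis_lutein", "trans_lutein", "zeaxanthin",
            "alpha_tocopherol", "gamma_tocopherol", "choline")
  nulls <- c("vitamin_a", "vitamin_b2", "vitamin_b6", "vitamin_b12",
             "vitamin_d", "lycopene", "carotene", "c10_0", "c12_0", "c14_0",
             "c16_0", "c18_0", "c20_0", "c22_0", "c18_4n3", "c22_4n6")
  stats::setNames(c(rep(0.8, length(hits)), rep(0, length(nulls))),
                  c(hits, nulls))
}

## Display metadata for the nutrient-profile table.
nutrient_catalog <- function() {
  data.frame(
    feature = c("c18_1n7", "c20_1n9", "c18_3n3", "c20_5n3", "c22_2n6",
                "c20_2n6", "c24_0", "cis_lutein", "trans_lutein",
                "zeaxanthin", "alpha_tocopherol", "gamma_tocopherol",
                "choline"),
    category = c(rep("Fatty Acids", 7),
                 rep("Antioxidants and Carotenoids", 3),
                 rep("Vitamins and Vitamin-Like Compounds", 3)),
    name = c("Vaccenic Acid", "Gondoic Acid", "Alpha Linolenic Acid (ALA)",
             "Eicosapentaenoic Acid (EPA)", "Docosadienoic Acid",
             "Eicosadienoic Acid", "Lignoceric Acid", "Lutein", "Lutein",
             "Zeaxanthin", "Vitamin E", "Vitamin E", "Choline"),
    stringsAsFactors = FALSE)
}

cortical_regions <- function() {
  c("banks_superior_temporal", "caudal_anterior_cingulate",
    "caudal_middle_frontal", "cuneus", "entorhinal", "frontal_pole",
    "fusiform", "inferior_parietal", "inferior_temporal", "insula",
    "isthmus_cingulate", "lateral_occipital", "lateral_orbitofrontal",
    "lingual", "medial_orbitofrontal", "middle_temporal", "paracentral",
    "parahippocampal", "pars_opercularis", "pars_orbitalis",
    "pars_triangularis", "pericalcarine", "postcentral",
    "posterior_cingulate", "precentral", "precuneus",
    "rostral_anterior_cingulate", "rostral_middle_frontal",
    "superior_frontal", "superior_parietal", "superior_temporal",
    "supramarginal", "temporal_pole", "transverse_temporal")
}

network_names <- function(n_networks = 7L) {
  base <- c("default_mode", "dorsal_attention", "frontoparietal", "limbic",
            "motor", "ventral_attention", "visual")
  if (n_networks <= length(base)) base[seq_len(n_networks)]
  else c(base, sprintf("network_%02d", seq_len(n_networks - length(base))))
}

connectivity_metrics <- function() {
  c("global_eff", "local_eff", "swp", "strength")
}

cognitive_names <- function(n) {
  base <- c("wasi_fsiq4", "wasi_pri", "wasi_vci", "wasi_bd", "wasi_mr",
            "wasi_voc", "wasi_sim", "dkefs_trails_1", "dkefs_trails_2",
            "dkefs_trails_3", "dkefs_trails_4", "dkefs_trails_5",
            "dkefs_trails_errors", "wms_imi", "wms_dmi")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("cog_%02d", seq_len(n - length(base))))
}

feature_names_volume <- function(n) {
  if (n == 68L) {
    reg <- cortical_regions()
    paste0("vol_", rep(reg, each = 2), c("_lh", "_rh"))
  } else sprintf("vol_%03d", seq_len(n))
}

feature_names_dti <- function(n) {
  if (n == 34L) paste0("fa_", cortical_regions())
  else sprintf("fa_%03d", seq_len(n))
}

feature_names_metab <- function(n) {
  base <- c("mrs_choline", "mrs_creatine", "mrs_naa")
  if (n <= 3L) base[seq_len(n)] else c(base, sprintf("mrs_%02d", seq_len(n - 3L)))
}

## Feature manifest: one row per generated column with its domain tag, its
## health direction (+1 higher-is-better, -1 for reverse-scored cognitive
## measures and the network graph metrics that run opposite to brain
## health) and the planted (signed) delayed-minus-accelerated d.
build_manifest <- function(cfg) {
  nets <- c(network_names(cfg$n_networks), "whole_brain")
  mets <- connectivity_metrics()
  conn <- as.vector(t(outer(nets, mets, function(a, b) paste("conn", a, b, sep = "_"))))
  conn_eff <- unlist(lapply(nets, function(nw) {
    if (nw == "whole_brain") {
      rep(cfg$effect_size_brain[["connectivity"]], 4L)
    } else {
      ## network-level reversals: strength and efficiencies favor accelerated
      d <- cfg$effect_size_brain[["connectivity"]]
      c(global_eff = -d, local_eff = -d, swp = d, strength = -d)
    }
  }))
  cogn <- cognitive_names(cfg$n_cognitive)
  cog_dir <- rep(1, cfg$n_cognitive)
  cog_dir[cfg$reverse_scored] <- -1
  man <- rbind(
    data.frame(feature = feature_names_volume(cfg$n_volumes),
               domain = "structure.volume", direction = 1,
               effect = cfg$effect_size_brain[["volume"]]),
    data.frame(feature = feature_names_dti(cfg$n_tracts),
               domain = "structure.dti", direction = 1,
               effect = cfg$effect_size_brain[["dti"]]),
    data.frame(feature = feature_names_metab(cfg$n_metabolites),
               domain = "metabolism", direction = 1,
               effect = cfg$effect_size_brain[["metabolism"]]),
    data.frame(feature = conn, domain = "connectivity",
               direction = ifelse(sign(conn_eff) < 0, -1, 1),
               effect = as.numeric(conn_eff)),
    data.frame(feature = cogn, domain = "cognition", direction = cog_dir,
               effect = cfg$effect_size_cognitive * cog_dir),
    data.frame(feature = names(cfg$nutrient_panel), domain = "nutrient",
               direction = 1, effect = as.numeric(cfg$nutrient_panel))
  )
  rownames(man) <- NULL
  man
}

#' Generate a synthetic two-phenotype cohort
#'
#' Draws a participant-by-feature table with planted accelerated/delayed
#' group structure: every feature is Gaussian (within-group SD 1) with a
#' group-mean shift equal to its planted standardized difference; brain age
#' is drawn per group around the configured means; covariates are drawn
#' independently of group membership so they cannot explain the phenotypes.
#'
#' @param config a [cohort_config()] object.
#' @return a list with components `cohort` (class `cohort_table`: a
#'   data.frame of participant_id, covariates, features and brain_age, with
#'   the feature manifest in `attr(, "manifest")`) and `truth` (class
#'   `planted_truth`: group labels, per-feature planted effects and
#'   per-participant Watts-Strogatz rewiring parameters).
#' @examples
#' cc <- cohort_config(n_participants = 40, seed = 7)
#' g <- generate_cohort(cc)
#' table(g$truth$group)
#' @export
generate_cohort <- function(config) {
  stop_if(!inherits(config, "cohort_config"), "'config' must come from cohort_config()")
  cfg <- config
  man <- build_manifest(cfg)
  n <- cfg$n_participants

  with_seed(cfg$seed, {
    n_del <- round(n * cfg$group_fraction)
    stop_if(n_del < 1 || n_del > n - 1,
            "'group_fraction' leaves an empty group at this cohort size")
    group <- rep("accelerated", n)
    group[sample.int(n, n_del)] <- "delayed"
    sgn <- ifelse(group == "delayed", 0.5, -0.5)

    X <- matrix(stats::rnorm(n * nrow(man)), n, nrow(man))
    X <- X + outer(sgn, man$effect)
    colnames(X) <- man$feature

    ba_mean <- ifelse(group == "delayed",
                      cfg$brain_age_means[["delayed"]],
                      cfg$brain_age_means[["accelerated"]])
    brain_age <- stats::rnorm(n, ba_mean, cfg$brain_age_sd)

    cs <- cfg$covariate_spec
    covars <- data.frame(
      age = stats::runif(n, cs$age[1], cs$age[2]),
      sex = factor(sample(c("F", "M"), n, replace = TRUE)),
      education = stats::rnorm(n, cs$education[1], cs$education[2]),
      income = pmin(pmax(round(stats::rnorm(n, cs$income[1], cs$income[2])), 1), 10),
      bmi = stats::rnorm(n, cs$bmi[1], cs$bmi[2])
    )

    beta_ws <- ifelse(group == "delayed",
                      cfg$ws_beta[["delayed"]],
                      cfg$ws_beta[["accelerated"]])

    cohort <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                         covars, X, brain_age = brain_age,
                         check.names = FALSE, stringsAsFactors = FALSE)
    attr(cohort, "manifest") <- man
    attr(cohort, "covariates") <- c("age", "sex", "education", "income", "bmi")
    class(cohort) <- c("cohort_table", "data.frame")

    truth <- list(participant_id = cohort$participant_id,
                  group = group,
                  effects = stats::setNames(man$effect, man$feature),
                  beta_ws = beta_ws,
                  config = cfg)
    class(truth) <- "planted_truth"
    list(cohort = cohort, truth = truth)
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("Synthetic cohort: %d participants, %d features (+%d covariates, brain_age)\n",
              nrow(x), nrow(man), length(attr(x, "covariates"))))
  print(table(man$domain))
  invisible(x)
}

## ----- BOLD-like time-series panels -------------------------------------

## Watts-Strogatz ring adjacency: nodes ordered so each intrinsic network
## occupies a contiguous block, hence most lattice edges are within-network.
ws_adjacency <- function(n_nodes, k, beta) {
  g <- igraph::sample_smallworld(dim = 1, size = n_nodes, nei = max(1L, k %/% 2L),
                                 p = beta, loops = FALSE, multiple = FALSE)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

#' Simulate one BOLD-like node-by-time panel
#'
#' Samples multivariate-normal time points whose target correlation places
#' `edge_cor` on the edges of a Watts-Strogatz graph (rewiring probability
#' `beta`) and zero elsewhere; the target is projected to the nearest valid
#' correlation matrix by eigenvalue clipping before Cholesky sampling. With
#' `edge_cor = 0` the panel is independent noise.
#'
#' @param n_nodes,n_timepoints panel dimensions; `n_timepoints` must be at
#'   least 4 for downstream Fisher-Z standardization.
#' @param beta Watts-Strogatz rewiring probability in `[0, 1]`.
#' @param k even ring-neighborhood size.
#' @param edge_cor target correlation on graph edges.
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @return node-by-time numeric matrix with node ids as row names.
#' @export
bold_panel <- function(n_nodes, n_timepoints, beta, k = 10L, edge_cor = 0.5,
                       seed = 1L) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 4L)
  stop_if(n_timepoints <= 3,
          "'n_timepoints' must exceed 3: sigma = 1/sqrt(n - 3) is undefined otherwise")
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 4L)
  check_scalar(beta, "beta", lo = 0, hi = 1)
  check_scalar(edge_cor, "edge_cor", lo = 0, hi = 0.99)
  with_seed(seed, {
    A <- ws_adjacency(n_nodes, k, beta)
    Sigma <- diag(n_nodes) + edge_cor * A
    ev <- eigen(Sigma, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-6)
    Sigma <- ev$vectors %*% (lam * t(ev$vectors))
    R <- stats::cov2cor((Sigma + t(Sigma)) / 2)
    X <- matrix(stats::rnorm(n_timepoints * n_nodes), n_timepoints, n_nodes) %*% chol(R)
    panel <- t(X)
    rownames(panel) <- sprintf("node_%03d", seq_len(n_nodes))
    attr(panel, "adjacency") <- A
    panel
  })
}

#' Simulate a participant's BOLD panel from planted truth
#'
#' Convenience wrapper over [bold_panel()] that looks up the participant's
#' group-specific Watts-Strogatz rewiring parameter: delayed-group
#' participants receive the low-rewiring (more small-world) substrate.
#'
#' @param truth `planted_truth` from [generate_cohort()].
#' @param config the matching [cohort_config()].
#' @param participant participant index.
#' @return node-by-time matrix (see [bold_panel()]).
#' @export
generate_timeseries <- function(truth, config, participant = 1L) {
  stop_if(!inherits(truth, "planted_truth"), "'truth' must come from generate_cohort()")
  participant <- check_count(participant, "participant")
  stop_if(participant > length(truth$beta_ws), "participant index out of range")
  bold_panel(config$n_nodes, config$n_timepoints,
             beta = truth$beta_ws[participant], k = config$ws_k,
             edge_cor = config$edge_cor,
             seed = derive_seed(config$seed, 1000L + participant))
}

#' Write a cohort and its sidecar manifest as delimited text
#'
#' @param x a `cohort_table`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(x, dir) {
  stop_if(!inherits(x, "cohort_table"), "'x' must be a cohort_table")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             manifest = file.path(dir, "feature_manifest.csv"))
  utils::write.csv(as.data.frame(x), paths["cohort"], row.names = FALSE)
  utils::write.csv(attr(x, "manifest"), paths["manifest"], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `cohort.csv` and `feature_manifest.csv`.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(dir) {
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  cohort$sex <- factor(cohort$sex)
  man <- utils::read.csv(file.path(dir, "feature_manifest.csv"),
                         stringsAsFactors = FALSE)
  attr(cohort, "manifest") <- man
  attr(cohort, "covariates") <- c("age", "sex", "education", "income", "bmi")
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}
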