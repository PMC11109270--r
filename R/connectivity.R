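## Functional-connectivity construction: Pearson correlations between node
## time series, Fisher-Z standardization by sqrt(n - 3), a Bonferroni
## threshold keeping significant positive correlations only, and rescaling
## of the surviving Z-scores to [0, 1] connection weights.

#' Pairwise Pearson correlation matrix of a node-by-time panel
#'
#' @param panel node-by-time numeric matrix; every node must have nonzero
#'   variance and at least 4 time points.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(panel) {
  stop_if(!is.matrix(panel) || any(!is.finite(panel)),
          "'panel' must be a finite node-by-time matrix")
  stop_if(ncol(panel) < 4L, "need at least 4 time points")
  v <- apply(panel, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(panel)[which(v == 0)]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance node(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(panel))
  diag(r) <- 1
  r
}

#' Fisher-Z transform and standardization of a correlation matrix
#'
#' Applies `Z = arctanh(r) / sigma` with `sigma = 1/sqrt(n - 3)`, the
#' variance-stabilized Fisher transform, so off-diagonal entries are
#' standard-normal under the null of zero correlation. The diagonal is
#' excluded (set to 0).
#'
#' @param r correlation matrix with all off-diagonal `|r| < 1`.
#' @param n number of time points (must be at least 4).
#' @return matrix of standardized Z-scores with zero diagonal.
#' @export
fisher_and_standardize <- function(r, n) {
  stop_if(n <= 3, "'n' must exceed 3: sigma = 1/sqrt(n - 3) is undefined")
  off <- abs(r) >= 1
  diag(off) <- FALSE
  stop_if(any(off), "off-diagonal |r| = 1: Fisher transform is infinite")
  z <- atanh(r) * sqrt(n - 3)
  diag(z) <- 0
  z
}

#' Bonferroni threshold keeping significant positive correlations
#'
#' Zeroes every entry except those exceeding the one-sided normal critical
#' value at level `alpha / m`; only positive correlations can survive.
#'
#' @param z standardized Z matrix from [fisher_and_standardize()].
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests; defaults to the `p(p-1)/2` unique node pairs.
#' @return sparse (mostly zero) Z matrix; attribute `z_crit` records the
#'   critical value used.
#' @export
bonferroni_positive_threshold <- function(z, alpha = 0.05, m = NULL) {
  check_scalar(alpha, "alpha")
  stop_if(alpha <= 0 || alpha >= 1, "'alpha' must lie in (0, 1)")
  p <- nrow(z)
  if (is.null(m)) m <- p * (p - 1) / 2
  stop_if(m < 1, "'m' must be at least 1")
  crit <- stats::qnorm(1 - alpha / m)
  out <- ifelse(z > crit, z, 0)
  diag(out) <- 0
  attr(out, "z_crit") <- crit
  attr(out, "m") <- m
  out
}

#' Rescale retained Z-scores to connection weights in [0, 1]
#'
#' Divides retained entries by the within-matrix maximum (default), so the
#' strongest connection gets weight 1 and zeros are preserved; `"minmax"`
#' instead maps the retained range onto (0, 1] via min-max over edges.
#'
#' @param z thresholded Z matrix (all retained entries positive).
#' @param method `"max"` (divide by maximum) or `"minmax"`.
#' @param network_label optional label stored on the result.
#' @return a `connectivity` matrix (symmetric, zero diagonal, weights in
#'   `[0, 1]`); if no edges survive the threshold the result carries
#'   `attr(, "empty") = TRUE` rather than failing silently.
#' @export
rescale_weights <- function(z, method = c("max", "minmax"),
                            network_label = "whole_brain") {
  method <- match.arg(method)
  stop_if(any(z < 0), "retained entries must be positive; threshold first")
  w <- unclass(z)
  attr(w, "z_crit") <- NULL
  attr(w, "m") <- NULL
  edges <- w[upper.tri(w)]
  edges <- edges[edges > 0]
  if (length(edges) == 0L) {
    w[] <- 0
  } else if (method == "max") {
    w <- w / max(edges)
  } else {
    lo <- min(edges)
    hi <- max(edges)
    rng <- if (hi > lo) hi - lo else 1
    pos <- w > 0
    ## keep the weakest retained edge strictly positive
    w[pos] <- 0.5 / length(edges) + (1 - 0.5 / length(edges)) *
      (w[pos] - lo) / rng
    w[!pos] <- 0
  }
  diag(w) <- 0
  structure(w, class = "connectivity", network = network_label,
            empty = length(edges) == 0L,
            provenance = list(rescale = method))
}

#' @export
print.connectivity <- function(x, ...) {
  m <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("Connectivity matrix '%s': %d nodes, %d edges%s\n",
              attr(x, "network"), nrow(x), m,
              if (isTRUE(attr(x, "empty"))) " [EMPTY]" else ""))
  invisible(x)
}

#' Default contiguous-block network partition
#'
#' Assigns the `n_nodes` parcellation nodes to seven intrinsic connectivity
#' networks in contiguous blocks (matching the block ordering used by the
#' synthetic BOLD generator).
#'
#' @param n_nodes parcellation size.
#' @param n_networks number of networks.
#' @return data.frame with columns `node_id`, `network`.
#' @export
default_partition <- function(n_nodes = 200L, n_networks = 7L) {
  nets <- network_names(n_networks)
  sizes <- rep(n_nodes %/% n_networks, n_networks)
  sizes[seq_len(n_nodes %% n_networks)] <- sizes[seq_len(n_nodes %% n_networks)] + 1L
  data.frame(node_id = sprintf("node_%03d", seq_len(n_nodes)),
             network = rep(nets, times = sizes),
             stringsAsFactors = FALSE)
}

#' Extract a network's principal submatrix
#'
#' @param W a `connectivity` matrix whose row names are node ids.
#' @param partition data.frame mapping `node_id` to `network`.
#' @param name network name, or `"whole_brain"` for the identity restriction.
#' @return a `connectivity` matrix on that network's nodes.
#' @export
extract_subnetwork <- function(W, partition, name) {
  if (identical(name, "whole_brain")) return(W)
  stop_if(!name %in% partition$network, sprintf("unknown network '%s'", name))
  ids <- partition$node_id[partition$network == name]
  idx <- match(ids, rownames(W))
  stop_if(any(is.na(idx)), "partition names nodes absent from the matrix")
  sub <- unclass(W)[idx, idx, drop = FALSE]
  structure(sub, class = "connectivity", network = name,
            empty = all(sub == 0), provenance = attr(W, "provenance"))
}

#' Build thresholded connectivity matrices from a BOLD panel
#'
#' Runs the full construction — Pearson correlations, Fisher-Z
#' standardization with `sigma = 1/sqrt(n - 3)`, one-sided Bonferroni
#' threshold over all unique node pairs, rescaling to `[0, 1]` — at the
#' whole-brain level, then extracts each network's principal submatrix
#' (threshold-then-extract; subnetworks are never re-thresholded).
#'
#' @param panel node-by-time matrix.
#' @param partition node-to-network map (default [default_partition()]).
#' @param alpha family-wise level of the Bonferroni threshold.
#' @param rescale weight-rescaling dialect, see [rescale_weights()].
#' @return named list of `connectivity` matrices: one per network plus
#'   `whole_brain`.
#' @examples
#' p <- bold_panel(40, 120, beta = 0.1, k = 6, seed = 2)
#' mats <- build_connectivity(p, default_partition(40))
#' sapply(mats, function(m) sum(m > 0) / 2)
#' @export
build_connectivity <- function(panel, partition = default_partition(nrow(panel)),
                               alpha = 0.05, rescale = "max") {
  r <- correlation_matrix(panel)
  z <- fisher_and_standardize(r, n = ncol(panel))
  zt <- bonferroni_positive_threshold(z, alpha = alpha)
  W <- rescale_weights(zt, method = rescale)
  rownames(W) <- colnames(W) <- rownames(panel)
  attr(W, "provenance") <- list(alpha = alpha, m = attr(zt, "m"),
                                z_crit = attr(zt, "z_crit"), rescale = rescale,
                                n_timepoints = ncol(panel))
  nets <- unique(partition$network)
  out <- lapply(nets, function(nw) extract_subnetwork(W, partition, nw))
  names(out) <- nets
  out$whole_brain <- W
  out
}

#' Write / read a connectivity matrix as dense delimited text
#'
#' @param W connectivity matrix.
#' @param file path of the CSV (node ids as header).
#' @return `write_connectivity` invisibly returns `file`;
#'   `read_connectivity` returns the matrix.
#' @export
write_connectivity <- function(W, file) {
  utils::write.csv(as.data.frame(unclass(W)), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(file) {
  d <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(d)
  rownames(m) <- colnames(m)
  structure(m, class = "connectivity", network = "whole_brain",
            empty = all(m == 0), provenance = list())
}
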