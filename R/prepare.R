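## Feature preparation: Frisch-Waugh-Lovell residualization against the
## covariates, Tukey Ladder-of-Powers normalization, and [0, 1] scaling —
## applied per column to brain, cognition and nutrient features alike.

#' Frisch-Waugh-Lovell residualization
#'
#' Removes covariate effects from an outcome by partialling: the returned
#' residuals are orthogonal to the intercept and to every covariate column,
#' and equal the least-squares residuals of `y` on `[1, X]`. Categorical
#' covariates enter as indicator columns via [stats::model.matrix()].
#'
#' @param y numeric outcome column.
#' @param X data.frame or matrix of covariates (rows aligned with `y`).
#' @return residual vector; attribute `coef` stores the fitted projection
#'   coefficients for lineage replay.
#' @export
fwl_residualize <- function(y, X) {
  stop_if(any(!is.finite(y)), "'y' contains missing or non-finite values")
  X <- as.data.frame(X)
  M <- if (ncol(X) == 0) matrix(1, length(y), 1,
                                dimnames = list(NULL, "(Intercept)"))
       else stats::model.matrix(~ ., data = X)
  stop_if(nrow(M) != length(y), "rows of 'X' must align with 'y'")
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    drop <- colnames(M)[qr_m$pivot[(qr_m$rank + 1):ncol(M)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qr_m, y)
  attr(res, "coef") <- qr.coef(qr_m, y)
  res
}

#' Tukey Ladder-of-Powers normalization
#'
#' Shifts the column to strictly positive support (subtracting the minimum
#' and adding a small offset, 1e-6 of the range), then chooses lambda from a
#' grid to maximize the Shapiro-Wilk W of the transformed column. The
#' transform is `x^lambda` for `lambda > 0`, `log(x)` for `lambda = 0` and
#' `-(x^lambda)` for `lambda < 0` — monotone increasing in every branch, so
#' within-column ranks are preserved exactly. Ties in W resolve toward the
#' lambda nearest 1.
#'
#' @param x non-constant numeric column.
#' @param grid candidate lambdas (default -2 to 2 in steps of 0.025).
#' @return list with `x` (transformed column), `lambda`, `shift` (the
#'   positivity offset applied) and `w` (attained Shapiro-Wilk statistic).
#' @export
tukey_ladder <- function(x, grid = seq(-2, 2, by = 0.025)) {
  stop_if(any(!is.finite(x)), "'x' contains missing or non-finite values")
  rng <- diff(range(x))
  stop_if(rng == 0, "'x' is constant: ladder transform undefined")
  shift <- -min(x) + 1e-6 * rng
  xp <- x + shift
  idx <- if (length(xp) > 5000) sample.int(length(xp), 5000) else seq_along(xp)
  ws <- vapply(grid, function(lam) {
    xt <- tukey_apply(xp, lam)
    if (any(!is.finite(xt)) || stats::sd(xt) == 0) return(-Inf)
    tryCatch(stats::shapiro.test(xt[idx])$statistic, error = function(e) -Inf)
  }, numeric(1))
  stop_if(all(!is.finite(ws)), "no ladder transform produced a finite column")
  best <- which(ws > max(ws) - 1e-12)
  lam <- grid[best[which.min(abs(grid[best] - 1))]]
  list(x = tukey_apply(xp, lam), lambda = lam, shift = shift,
       w = max(ws))
}

## One rung of the ladder, on already-positive input.
tukey_apply <- function(xpos, lambda) {
  if (lambda > 0) xpos^lambda
  else if (lambda == 0) log(xpos)
  else -(xpos^lambda)
}

#' Min-max scale a column onto [0, 1]
#'
#' @param x non-constant numeric column.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_scale <- function(x) {
  stop_if(any(!is.finite(x)), "'x' contains missing or non-finite values")
  rng <- range(x)
  stop_if(rng[1] == rng[2], "'x' is constant: cannot scale to [0, 1]")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Prepare a cohort's feature matrix
#'
#' Applies, per feature column: residualize against the covariates
#' (Frisch-Waugh-Lovell), Tukey Ladder-of-Powers toward normality, min-max
#' scale to `[0, 1]`. Brain, cognition and nutrient columns are all treated
#' identically. Every step is recorded in a lineage table (chosen lambda,
#' positivity shift, scaling bounds, residualization coefficients) so a
#' prepared column can be replayed on new data.
#'
#' @param cohort a `cohort_table` (or data.frame with a feature manifest
#'   attribute) from [generate_cohort()] / [read_cohort()].
#' @param covariates covariate column names; `sex` and other factors enter
#'   as indicators.
#' @param domains domain tags to prepare.
#' @return an object of class `prepared_features`: `values` (participants x
#'   features in `[0, 1]`), `residuals` (FWL residual matrix), `lineage`,
#'   `manifest`, `participant_id`, and the raw `brain_age` column carried
#'   through untouched.
#' @export
prepare_features <- function(cohort,
                             covariates = attr(cohort, "covariates"),
                             domains = c("structure.volume", "structure.dti",
                                         "metabolism", "connectivity",
                                         "cognition", "nutrient")) {
  man <- attr(cohort, "manifest")
  stop_if(is.null(man), "'cohort' carries no feature manifest")
  stop_if(anyDuplicated(cohort$participant_id) > 0, "duplicate participant ids")
  keep <- man[man$domain %in% domains, , drop = FALSE]
  stop_if(nrow(keep) == 0, "no features in the requested domains")
  X <- cohort[, covariates, drop = FALSE]
  stop_if(any(!stats::complete.cases(X)), "covariates contain missing values")

  vals <- matrix(NA_real_, nrow(cohort), nrow(keep),
                 dimnames = list(cohort$participant_id, keep$feature))
  resids <- vals
  lineage <- vector("list", nrow(keep))
  coefs <- vector("list", nrow(keep))
  for (i in seq_len(nrow(keep))) {
    f <- keep$feature[i]
    step <- function(expr) tryCatch(expr, error = function(e)
      stop(sprintf("feature '%s': %s", f, conditionMessage(e)), call. = FALSE))
    r <- step(fwl_residualize(cohort[[f]], X))
    if (diff(range(r)) <= 1e-8 * max(1, diff(range(cohort[[f]]))))
      stop(sprintf("feature '%s': constant after residualization", f),
           call. = FALSE)
    tk <- step(tukey_ladder(as.numeric(r)))
    sc <- step(minmax_scale(tk$x))
    resids[, i] <- r
    vals[, i] <- sc
    coefs[[i]] <- attr(r, "coef")
    lineage[[i]] <- data.frame(feature = f, domain = keep$domain[i],
                               lambda = tk$lambda, shift = tk$shift,
                               t_min = min(tk$x), t_max = max(tk$x),
                               stringsAsFactors = FALSE)
  }
  lineage <- do.call(rbind, lineage)
  names(coefs) <- keep$feature
  structure(list(values = vals, residuals = resids, lineage = lineage,
                 coef = coefs, manifest = keep, covariates = covariates,
                 participant_id = cohort$participant_id,
                 brain_age = cohort[["brain_age"]]),
            class = "prepared_features")
}

#' @export
print.prepared_features <- function(x, ...) {
  cat(sprintf("Prepared feature matrix: %d participants x %d features in [0,1]\n",
              nrow(x$values), ncol(x$values)))
  cat("  lambda range:", paste(range(x$lineage$lambda), collapse = " .. "), "\n")
  invisible(x)
}

## Replay recorded preparation steps on new rows (used by predict()).
replay_preparation <- function(prep, newdata) {
  X <- newdata[, prep$covariates, drop = FALSE]
  M <- stats::model.matrix(~ ., data = as.data.frame(X))
  out <- matrix(NA_real_, nrow(newdata), nrow(prep$lineage),
                dimnames = list(NULL, prep$lineage$feature))
  for (i in seq_len(nrow(prep$lineage))) {
    ln <- prep$lineage[i, ]
    cf <- prep$coef[[ln$feature]]
    r <- newdata[[ln$feature]] - as.numeric(M[, names(cf), drop = FALSE] %*% cf)
    xt <- tukey_apply(pmax(r + ln$shift, 1e-12), ln$lambda)
    out[, i] <- (xt - ln$t_min) / (ln$t_max - ln$t_min)
  }
  out
}
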