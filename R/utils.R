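#' @keywords internal
"_PACKAGE"

## Internal validation helpers shared across modules.

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  stop_if(length(x) != 1L || !is.finite(x) || x < min || x != round(x),
          sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  stop_if(length(x) != 1L || !is.finite(x) || x < lo || x > hi,
          sprintf("'%s' must be a finite scalar in [%s, %s]", name, lo, hi))
  as.numeric(x)
}

## Symmetric, non-negative, zero-diagonal weighted adjacency.
check_adjacency <- function(W, name = "W") {
  stop_if(!is.matrix(W) || nrow(W) != ncol(W), sprintf("'%s' must be a square matrix", name))
  stop_if(any(!is.finite(W)), sprintf("'%s' contains non-finite entries", name))
  stop_if(max(abs(W - t(W))) > 1e-10, sprintf("'%s' must be symmetric", name))
  stop_if(any(diag(W) != 0), sprintf("'%s' must have a zero diagonal", name))
  stop_if(any(W < 0), sprintf("'%s' must be non-negative", name))
  W
}

## Counter-based derivation of per-stage seeds from one master seed, kept
## inside the 32-bit integer range so set.seed() always accepts them.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 10007) %% 2147483647)
}

## Run an expression under a local RNG state (restores .Random.seed after).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
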