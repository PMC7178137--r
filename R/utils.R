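# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Column-wise z-scoring that tolerates constant columns (scale set to 1 so
# the column contributes nothing to Euclidean distances instead of NaN).
zscore_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}

zscore_apply <- function(x, fit) {
  sweep(sweep(x, 2, fit$center, "-"), 2, fit$scale, "/")
}

# Stratified fold assignment: within each class samples are shuffled, then
# folds are dealt round-robin with a carry-over counter across classes so that
# overall fold sizes differ by at most one.
stratified_folds <- function(y, n_folds, seed) {
  stopifnot(n_folds >= 2, length(y) >= n_folds)
  fold <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
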