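# Resampling module: class re-balancing of labelled sample sets.
#
# Two undersampling strategies aimed at class-overlap regions:
#   * RENN  - repeated edited nearest neighbours: iteratively remove samples
#     whose local 3-NN label vote contradicts their own label, until a
#     fixed point.
#   * IHT   - instance hardness threshold: score every sample by
#     IH = 1 - p(own label | features, estimator) from out-of-fold logistic
#     predictions and remove the hardest majority-class samples until the
#     classes balance.
#
# Features are z-scored internally before any Euclidean distance or
# estimator fit; raw values in the sample set are never modified.

resample_report <- function(method, before, after, removed_ids,
                            iterations = NA_integer_, estimator_spec = NA_character_) {
  structure(
    list(method = method,
         before_counts = c(positives = before[["positives"]], negatives = before[["negatives"]]),
         after_counts = c(positives = after[["positives"]], negatives = after[["negatives"]]),
         removed_ids = removed_ids,
         iterations = iterations,
         estimator_spec = estimator_spec),
    class = "resample_report"
  )
}

#' @export
print.resample_report <- function(x, ...) {
  cat(sprintf("%s: %d/%d -> %d/%d (pos/neg), %d removed\n",
              toupper(x$method),
              x$before_counts[1], x$before_counts[2],
              x$after_counts[1], x$after_counts[2], length(x$removed_ids)))
  invisible(x)
}

class_counts <- function(y) c(positives = sum(y == 1L), negatives = sum(y == 0L))

#' Repeated edited nearest neighbours
#'
#' Each sweep finds, for every removable sample, its `k` nearest neighbours
#' (Euclidean distance in z-scored feature space, excluding itself) among
#' the current set and marks the sample for removal when at least two of the
#' three neighbour labels disagree with its own. All marked samples are
#' removed simultaneously at the end of the sweep; sweeps repeat until
#' nothing is removed or `max_iter` is reached.
#'
#' @param s a [sample_set()] with at least `k + 1` samples.
#' @param k neighbourhood size (default 3).
#' @param target `"negatives_only"` restricts removal to the majority
#'   (non-interface) class; `"all"` edits both classes.
#' @param max_iter sweep limit.
#' @return list with elements `samples` (the edited [sample_set()]) and
#'   `report` (a `resample_report`).
#' @export
renn_edit <- function(s, k = 3, target = c("negatives_only", "all"),
                      max_iter = 100) {
  target <- match.arg(target)
  n <- nrow(s$x)
  if (n < k + 1) stop("need at least ", k + 1, " samples for ", k, "-NN editing")
  before <- class_counts(s$y)
  keys <- sample_keys(s)
  keep <- seq_len(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # z-scores are re-fitted on the current set each sweep, so a converged
    # set is an exact fixed point of the whole procedure
    xx <- s$x[keep, , drop = FALSE]
    zz <- zscore_apply(xx, zscore_fit(xx))
    yy <- s$y[keep]
    d <- as.matrix(dist(zz))
    diag(d) <- Inf
    votes_differ <- vapply(seq_along(keep), function(i) {
      nb <- order(d[i, ], keys[keep])[seq_len(k)]
      sum(yy[nb] != yy[i])
    }, integer(1))
    mark <- votes_differ >= 2L
    if (target == "negatives_only") mark <- mark & yy == 0L
    if (!any(mark)) break
    for (cl in c(0L, 1L)) {
      if (any(yy == cl) && all(mark[yy == cl])) {
        stop("editing would empty the ",
             if (cl == 1L) "positive" else "negative", " class")
      }
    }
    keep <- keep[!mark]
    if (iter >= max_iter || length(keep) < k + 1) break
  }
  removed <- setdiff(seq_len(n), keep)
  out <- sample_subset(s, keep)
  list(samples = out,
       report = resample_report("renn", before, class_counts(out$y),
                                keys[removed], iterations = iter))
}

#' Instance hardness scores
#'
#' Instance hardness of sample (x_i, y_i) is IH = 1 - p(y_i | x_i, h),
#' the complement of the probability the estimator h assigns to the sample's
#' own label. Probabilities are out-of-fold: the data are split into
#' stratified folds and each fold is scored by a logistic-regression
#' estimator fitted on the remaining folds (features z-scored with
#' training-fold statistics), so no sample is scored by a model that saw it.
#'
#' @param s a [sample_set()] containing both classes.
#' @param folds number of stratified folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return numeric vector of scores in \[0, 1\], one per sample; attribute
#'   `estimator` records the estimator specification.
#' @export
instance_hardness <- function(s, folds = 5, seed = 42) {
  y <- s$y
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(folds >= 2)
  fold <- stratified_folds(y, folds, seed)
  p_own <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fit_z <- zscore_fit(s$x[tr, , drop = FALSE])
    ztr <- cbind(1, zscore_apply(s$x[tr, , drop = FALSE], fit_z))
    zte <- cbind(1, zscore_apply(s$x[!tr, , drop = FALSE], fit_z))
    fit <- suppressWarnings(glm.fit(ztr, y[tr], family = binomial()))
    if (!fit$converged) {
      message("logistic estimator did not converge in fold ", f,
              "; using final iterate")
    }
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    p1 <- plogis(drop(zte %*% beta))
    p_own[!tr] <- ifelse(y[!tr] == 1L, p1, 1 - p1)
  }
  scores <- 1 - p_own
  scores <- pmin(pmax(scores, 0), 1)
  attr(scores, "estimator") <- sprintf(
    "logistic regression, %d stratified folds, seed %d", folds, seed)
  scores
}

#' Instance hardness threshold undersampling
#'
#' Removes the hardest majority-class samples (highest instance hardness,
#' ties broken by ascending provenance key) until the class sizes reach the
#' requested ratio; with `ratio = 1` the classes end exactly equal. The
#' minority class is never touched.
#'
#' @param s a [sample_set()].
#' @param scores per-sample hardness from [instance_hardness()]; computed
#'   with defaults when omitted.
#' @param ratio target majority/minority size ratio after removal.
#' @return list with `samples` and `report`, as [renn_edit()].
#' @export
iht_resample <- function(s, scores = instance_hardness(s), ratio = 1.0) {
  stopifnot(length(scores) == nrow(s$x), ratio > 0)
  before <- class_counts(s$y)
  maj_label <- if (before[["negatives"]] >= before[["positives"]]) 0L else 1L
  n_maj <- sum(s$y == maj_label)
  n_min <- length(s$y) - n_maj
  target_maj <- ceiling(n_min * ratio)
  if (target_maj > n_maj) {
    stop("ratio ", ratio, " would require removing minority samples")
  }
  n_remove <- n_maj - target_maj
  keys <- sample_keys(s)
  maj <- which(s$y == maj_label)
  maj <- maj[order(-scores[maj], keys[maj])]
  removed <- maj[seq_len(n_remove)]
  keep <- setdiff(seq_len(nrow(s$x)), removed)
  out <- sample_subset(s, keep)
  list(samples = out,
       report = resample_report("iht", before, class_counts(out$y),
                                keys[removed],
                                estimator_spec = attr(scores, "estimator") %||%
                                  "externally supplied scores"))
}
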