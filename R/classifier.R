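# Classifier module: gradient-boosted trees (additive tree ensemble under a
# binary logistic objective with leaf-count and leaf-weight regularisation)
# and the stratified 10-fold cross-validation protocol.
#
# Training delegates to the xgboost engine; the additive contract (the
# margin of a sample is the sum of its leaf scores over all trees, passed
# through the logistic link) is part of the tested interface.

#' Boosted-tree model configuration
#'
#' @param n_trees number of boosting rounds K.
#' @param learning_rate shrinkage applied to each tree's leaf scores.
#' @param max_depth maximum tree depth.
#' @param reg_lambda L2 penalty on leaf weights.
#' @param reg_gamma penalty per leaf (minimum split loss reduction).
#' @param threshold decision threshold on the logistic score.
#' @param seed engine RNG seed.
#' @return a `boosted_config` list.
#' @export
boosted_config <- function(n_trees = 200, learning_rate = 0.1, max_depth = 4,
                           reg_lambda = 1, reg_gamma = 0, threshold = 0.5,
                           seed = 42) {
  stopifnot(n_trees >= 1, learning_rate > 0, reg_lambda >= 0, reg_gamma >= 0)
  structure(list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth), reg_lambda = reg_lambda,
                 reg_gamma = reg_gamma, threshold = threshold,
                 seed = as.integer(seed)),
            class = "boosted_config")
}

xgb_params <- function(config) {
  xgboost::xgb.params(
    objective = "binary:logistic",
    learning_rate = config$learning_rate,
    max_depth = config$max_depth,
    reg_lambda = config$reg_lambda,
    gamma = config$reg_gamma,
    # pin the prior margin at 0 so a sample's margin is exactly the sum of
    # its leaf scores across trees
    base_score = 0.5,
    nthread = 1,
    seed = config$seed
  )
}

#' Train a boosted-tree interface classifier
#'
#' @param s a [sample_set()] with both classes present.
#' @param config a [boosted_config()].
#' @return a `ppi_model`: the fitted booster plus the configuration and
#'   feature-column names.
#' @export
ppi_train <- function(s, config = boosted_config()) {
  if (length(unique(s$y)) < 2) stop("training data contain a single class")
  d <- xgboost::xgb.DMatrix(s$x, label = s$y, nthread = 1)
  booster <- xgboost::xgb.train(xgb_params(config), d,
                                nrounds = config$n_trees, verbose = 0)
  structure(list(booster = booster, config = config,
                 feature_names = colnames(s$x),
                 class_counts = class_counts(s$y)),
            class = "ppi_model")
}

#' @export
print.ppi_model <- function(x, ...) {
  cat(sprintf("ppi_model: %d trees, depth %d, eta %g (trained on %d pos / %d neg)\n",
              x$config$n_trees, x$config$max_depth, x$config$learning_rate,
              x$class_counts[1], x$class_counts[2]))
  invisible(x)
}

#' Predict with a fitted interface classifier
#'
#' @param object a `ppi_model`.
#' @param newdata a [sample_set()] or numeric matrix with the training
#'   feature columns.
#' @param type `"prob"` (logistic score), `"class"` (0/1 at the configured
#'   threshold) or `"margin"` (raw leaf-score sum).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.ppi_model <- function(object, newdata, type = c("prob", "class", "margin"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "sample_set")) newdata$x else as.matrix(newdata)
  d <- xgboost::xgb.DMatrix(x, nthread = 1)
  if (type == "margin") {
    return(predict(object$booster, d, outputmargin = TRUE))
  }
  p <- predict(object$booster, d)
  if (type == "class") as.integer(p >= object$config$threshold) else p
}

#' Save / load a fitted model
#'
#' The booster is persisted in the engine's native JSON dump next to a
#' sidecar recording the configuration and feature columns.
#'
#' @param model a `ppi_model`.
#' @param dir directory to create/use.
#' @return `dir` / the reloaded `ppi_model`.
#' @export
save_ppi_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.json"))
  jsonlite::write_json(
    list(config = unclass(model$config), feature_names = model$feature_names,
         class_counts = as.list(model$class_counts)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname save_ppi_model
#' @export
load_ppi_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg <- do.call(boosted_config, as.list(meta$config))
  structure(list(booster = xgboost::xgb.load(file.path(dir, "booster.json")),
                 config = cfg, feature_names = meta$feature_names,
                 class_counts = unlist(meta$class_counts)),
            class = "ppi_model")
}

#' Stratified cross-validation plan
#'
#' Assigns every sample to exactly one of `n_folds` folds, preserving class
#' proportions per fold; overall fold sizes differ by at most one.
#'
#' @param y 0/1 label vector.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed.
#' @return a `cv_plan`: list with `n_folds`, `assignment`, `seed`.
#' @export
cv_plan <- function(y, n_folds = 10, seed = 42) {
  structure(list(n_folds = as.integer(n_folds),
                 assignment = stratified_folds(y, n_folds, seed),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Cross-validated training and evaluation
#'
#' Runs the 10-fold protocol: each fold is held out once, the model is
#' trained on the other nine, and the pooled confusion matrix is accumulated
#' over held-out predictions.
#'
#' Two orderings of resampling and splitting are available.
#' `"split_then_resample"` (recommended) applies the resampler to each
#' training split only, so held-out folds are never edited and no
#' information leaks. `"resample_then_split"` applies the resampler once to
#' the full set before folding — this reproduces evaluation protocols that
#' balance the whole dataset first, and a leakage warning is emitted.
#'
#' @param s a [sample_set()].
#' @param config a [boosted_config()].
#' @param n_folds,seed folds and RNG seed for the plan (ignored if `plan`
#'   given).
#' @param plan optional [cv_plan()] (for `resample_then_split` it must match
#'   the post-resampling sample count).
#' @param resampler NULL, `"renn"`, `"iht"`, or a function
#'   `sample_set -> list(samples=, report=)`.
#' @param mode resampling/split ordering, see Details.
#' @return list with `per_fold` (confusion matrices), `pooled` (confusion),
#'   `metrics` (pooled `ppi_metrics`), `per_fold_metrics` (list),
#'   `predictions` (0/1, aligned with evaluated samples), `plan`, and
#'   `resample_reports`.
#' @export
cross_validate <- function(s, config = boosted_config(), n_folds = 10,
                           seed = 42, plan = NULL, resampler = NULL,
                           mode = c("split_then_resample", "resample_then_split")) {
  mode <- match.arg(mode)
  resample_fn <- resampler_function(resampler, seed)
  reports <- list()
  if (!is.null(resample_fn) && mode == "resample_then_split") {
    warning("resampling before the split leaks information across folds; ",
            "use mode = \"split_then_resample\" for honest estimates",
            call. = FALSE)
    res <- resample_fn(s)
    s <- res$samples
    reports <- c(reports, list(res$report))
  }
  if (is.null(plan)) plan <- cv_plan(s$y, n_folds, seed)
  stopifnot(length(plan$assignment) == nrow(s$x))
  per_fold <- vector("list", plan$n_folds)
  pred <- integer(nrow(s$x))
  for (f in seq_len(plan$n_folds)) {
    tr_idx <- which(plan$assignment != f)
    te_idx <- which(plan$assignment == f)
    train_s <- sample_subset(s, tr_idx)
    if (length(unique(train_s$y)) < 2) {
      stop("training data for fold ", f, " contain a single class")
    }
    if (!is.null(resample_fn) && mode == "split_then_resample") {
      res <- resample_fn(train_s)
      train_s <- res$samples
      reports <- c(reports, list(res$report))
    }
    model <- ppi_train(train_s, config)
    pred[te_idx] <- predict(model, sample_subset(s, te_idx), type = "class")
    per_fold[[f]] <- confusion_from_labels(s$y[te_idx], pred[te_idx])
  }
  pooled <- Reduce(add_confusion, per_fold)
  list(per_fold = per_fold, pooled = pooled,
       metrics = compute_metrics(pooled),
       per_fold_metrics = lapply(per_fold, compute_metrics),
       predictions = pred, plan = plan, resample_reports = reports)
}

# Resolve the resampler argument to a function(sample_set) -> list(samples, report).
resampler_function <- function(resampler, seed) {
  if (is.null(resampler)) return(NULL)
  if (is.function(resampler)) return(resampler)
  switch(match.arg(resampler, c("iht", "renn")),
    iht = function(s) iht_resample(s, instance_hardness(s, seed = seed)),
    renn = function(s) renn_edit(s)
  )
}
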