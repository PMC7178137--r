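# Evaluation module: confusion matrices and the six derived performance
# measures (accuracy, sensitivity, precision, specificity, F-measure,
# Matthews correlation coefficient).

#' Confusion matrix for binary interface prediction
#'
#' Positives are interface residues. `tp`: interface predicted interface;
#' `fp`: non-interface predicted interface; `tn`: non-interface predicted
#' non-interface; `fn`: interface predicted non-interface.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return a `ppi_confusion` object.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(round(counts)), class = "ppi_confusion")
}

#' Confusion matrix from label vectors
#' @param truth,predicted integer vectors of 0/1 labels (1 = interface).
#' @return a `ppi_confusion` object.
#' @export
confusion_from_labels <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_matrix(
    tp = sum(truth == 1 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0),
    fp = sum(truth == 0 & predicted == 1),
    fn = sum(truth == 1 & predicted == 0)
  )
}

#' @export
print.ppi_confusion <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

# add two confusion matrices (pooling over CV folds)
add_confusion <- function(a, b) {
  confusion_matrix(a$tp + b$tp, a$tn + b$tn, a$fp + b$fp, a$fn + b$fn)
}

#' The six performance measures
#'
#' Computes accuracy, sensitivity (recall on interface residues), precision,
#' specificity, F-measure (harmonic mean of precision and sensitivity) and
#' the Matthews correlation coefficient from a confusion matrix. A measure
#' whose denominator is zero is reported as the sentinel 0 and named in the
#' `flags` field instead of raising an error, so degenerate cross-validation
#' folds do not abort a run.
#'
#' @param cm a [confusion_matrix()].
#' @return a `ppi_metrics` object: list with `acc`, `sen`, `pre`, `spe`,
#'   `f_measure`, `mcc` and `flags` (character vector of zero-denominator
#'   measures).
#' @export
compute_metrics <- function(cm) {
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("all-zero confusion matrix")
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      0
    } else num / den
  }
  acc <- (tp + tn) / total
  sen <- safe(tp, tp + fn, "sen")
  pre <- safe(tp, tp + fp, "pre")
  spe <- safe(tn, fp + tn, "spe")
  f <- safe(2 * pre * sen, pre + sen, "f_measure")
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- safe(as.numeric(tp) * tn - as.numeric(fp) * fn, mcc_den, "mcc")
  structure(list(acc = acc, sen = sen, pre = pre, spe = spe,
                 f_measure = f, mcc = mcc, flags = flags),
            class = "ppi_metrics")
}

#' @export
print.ppi_metrics <- function(x, digits = 3, ...) {
  v <- unlist(x[c("acc", "sen", "pre", "spe", "f_measure", "mcc")])
  print(round(v, digits))
  if (length(x$flags)) cat("zero-denominator:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' Stores the pooled confusion matrix and metrics at full precision and at
#' 3-decimal rounding, plus per-fold matrices when supplied.
#'
#' @param pooled a `ppi_metrics` for the pooled confusion matrix.
#' @param cm the pooled [confusion_matrix()].
#' @param path output path.
#' @param per_fold optional list of per-fold confusion matrices.
#' @param extra optional named list merged into the report (parameters etc.).
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(pooled, cm, path, per_fold = NULL, extra = NULL) {
  vals <- pooled[c("acc", "sen", "pre", "spe", "f_measure", "mcc")]
  rep <- list(
    pooled_confusion = cm[c("tp", "tn", "fp", "fn")],
    metrics = vals,
    metrics_rounded = lapply(vals, round, 3),
    flags = pooled$flags
  )
  if (!is.null(per_fold)) {
    rep$per_fold_confusion <- lapply(per_fold, function(m) m[c("tp", "tn", "fp", "fn")])
  }
  if (!is.null(extra)) rep <- c(rep, extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
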