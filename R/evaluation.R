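#' One-vs-rest confusion counts for a positive class
#'
#' Binarizes the multiclass labels (the positive class against everything
#' else pooled) and tabulates true/false positives and negatives.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_class The class treated as positive.
#' @return An object of class `confusion_counts` with fields
#'   `class_label`, `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L)
    stopf("y_true and y_pred must be equal-length, non-empty")
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  structure(list(class_label = as.character(positive_class),
                 TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' The six one-vs-rest performance metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FN+TN+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision/PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)` and the F1
#' score, the harmonic mean of precision and sensitivity. A metric whose
#' denominator is zero is returned as `NA` (undefined) with the affected
#' names recorded in the `"undefined"` attribute -- never as a silent 0.
#'
#' @param cc A [confusion_counts()] object, or a list/vector with elements
#'   `TP`, `TN`, `FP`, `FN`.
#' @return Object of class `metrics_row`: named numeric vector with
#'   elements accuracy, sensitivity, specificity, f1, ppv, npv.
#' @export
metrics_from_counts <- function(cc) {
  tp <- cc[["TP"]]; tn <- cc[["TN"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]
  total <- tp + tn + fp + fn
  if (total == 0) stopf("all-zero confusion counts")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  # harmonic mean of precision and sensitivity, in the algebraically
  # equivalent count form (stable when both are 0)
  f1 <- if (is.na(ppv) || is.na(sens)) NA_real_
        else 2 * tp / (2 * tp + fp + fn)
  out <- c(accuracy = (tp + tn) / total, sensitivity = sens,
           specificity = spec, f1 = f1, ppv = ppv, npv = npv)
  undef <- names(out)[is.na(out)]
  if (length(undef)) attr(out, "undefined") <- undef
  class(out) <- "metrics_row"
  out
}

#' Macro (unweighted per-class) average of metric rows
#'
#' @param rows List of [metrics_from_counts()] rows, one per class.
#' @return A `metrics_row` of unweighted means.
#' @export
macro_summary <- function(rows) {
  if (!length(rows)) stopf("need at least one metrics row")
  m <- do.call(rbind, lapply(rows, unclass))
  out <- colMeans(m)
  class(out) <- "metrics_row"
  out
}

#' @export
print.metrics_row <- function(x, ...) {
  v <- unclass(x); attr(v, "undefined") <- NULL
  print(round(v, 4))
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps a threshold over that class's score column
#' (class vs all others pooled) and accumulates true/false positive rates;
#' AUC by the trapezoidal rule. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores Numeric matrix, rows x classes, with class names as
#'   column names.
#' @param y_true Label vector of length `nrow(scores)`.
#' @return Object of class `roc_ovr`: per-class list of `fpr`, `tpr`
#'   (nondecreasing from 0 to 1) and `auc`.
#' @export
roc_ovr <- function(scores, y_true) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y_true)) stopf("score rows must match labels")
  if (is.null(colnames(scores))) stopf("score matrix needs class column names")
  out <- lapply(colnames(scores), function(cl) {
    pos <- y_true == cl
    P <- sum(pos); N <- sum(!pos)
    if (P == 0 || N == 0)
      return(list(class = cl, fpr = c(0, 1), tpr = c(0, 1), auc = NA_real_))
    s <- scores[, cl]
    ord <- order(s, decreasing = TRUE)
    tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
    # collapse threshold ties: keep the last point of each tied score run
    keep <- c(diff(s[ord]) != 0, TRUE)
    tpr <- c(0, tp[keep] / P); fpr <- c(0, fp[keep] / N)
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    list(class = cl, fpr = fpr, tpr = tpr, auc = auc)
  })
  structure(stats::setNames(out, colnames(scores)), class = "roc_ovr")
}

#' @export
print.roc_ovr <- function(x, ...) {
  for (r in x) cat(sprintf("class %s: AUC %.4f\n", r$class, r$auc))
  invisible(x)
}

#' Plot one-vs-rest ROC curves
#'
#' @param x A `roc_ovr` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_ovr <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "false positive rate", ylab = "true positive rate", ...)
  cols <- seq_along(x) + 1L
  for (i in seq_along(x)) graphics::lines(x[[i]]$fpr, x[[i]]$tpr, col = cols[i])
  graphics::legend("bottomright",
                   sprintf("%s (AUC %.3f)", names(x),
                           vapply(x, `[[`, numeric(1), "auc")),
                   col = cols, lty = 1)
  invisible(x)
}

#' Permutation feature importance
#'
#' Mean drop in accuracy on the given labeled table when one feature
#' column is shuffled, over `n_repeats` shuffles per feature. Applicable
#' uniformly to any fitted classifier; deterministic given the seed.
#'
#' @param model A `gait_model`.
#' @param table Labeled feature `data.frame`.
#' @param n_repeats Shuffles per feature (default 20).
#' @param seed RNG seed (default 22).
#' @return Named numeric vector of mean accuracy drops, one per feature.
#' @export
permutation_importance <- function(model, table, n_repeats = 20L, seed = 22L) {
  d <- prep_xy(table)
  if (is.null(d$y)) stopf("permutation importance needs a labeled table")
  y <- factor(as.character(table$stage), levels = model$levels)
  baseline <- mean(stats::predict(model, d$x) == y)
  feats <- model$feature_names
  with_seed(seed, {
    drops <- vapply(feats, function(fn) {
      accs <- vapply(seq_len(n_repeats), function(r) {
        xp <- d$x
        xp[, fn] <- xp[sample.int(nrow(xp)), fn]
        mean(stats::predict(model, xp) == y)
      }, numeric(1))
      baseline - mean(accs)
    }, numeric(1))
    drops
  })
}

#' Full one-vs-rest evaluation of a model on a labeled table
#'
#' Convenience wrapper producing, per class, the confusion counts and
#' metric row, the macro summary, and the ROC/AUC result.
#'
#' @param model A `gait_model`.
#' @param table Labeled feature `data.frame`.
#' @return List with `counts` (per class), `metrics` (per class), `macro`
#'   and `roc`.
#' @export
evaluate_model <- function(model, table) {
  d <- prep_xy(table)
  y <- factor(as.character(table$stage), levels = model$levels)
  pred <- stats::predict(model, d$x)
  score <- stats::predict(model, d$x, type = "score")
  classes <- model$levels
  counts <- lapply(classes, function(cl) confusion_counts(y, pred, cl))
  names(counts) <- classes
  metrics <- lapply(counts, metrics_from_counts)
  list(counts = counts, metrics = metrics,
       macro = macro_summary(metrics), roc = roc_ovr(score, y))
}
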