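#' Default hyper-parameter grid for a model family
#'
#' KNN: number of neighbours 1-15 (odd), metric euclidean / manhattan /
#' minkowski, uniform or distance-weighted votes. SVM: cost C in
#' 0.01-100, linear or RBF kernel, "scale" gamma. GB: number of boosting
#' rounds in 1-100.
#'
#' @param family `"KNN"`, `"SVM"` or `"GB"`.
#' @return Named list of hyper-parameter value vectors.
#' @export
default_grid <- function(family) {
  switch(family,
    KNN = list(n_neighbors = c(1, 3, 5, 7, 9, 11, 13, 15),
               metric = c("euclidean", "manhattan", "minkowski"),
               weights = c("uniform", "distance")),
    SVM = list(C = c(0.01, 0.1, 1, 10, 100),
               kernel = c("linear", "rbf"),
               gamma = "scale"),
    GB = list(n_estimators = c(1, 2, 5, 20, 50, 100)),
    stopf("unknown model family '%s'", family))
}

#' Classifier training configuration
#'
#' @param family `"KNN"`, `"SVM"` or `"GB"`.
#' @param grid Hyper-parameter grid (named list of value vectors); defaults
#'   to [default_grid()] for the family.
#' @param cv_folds Number of stratified cross-validation folds (default 10).
#' @param seed RNG seed for fold assignment and stochastic model parts.
#' @param standardize Z-score the feature columns (fit on training folds
#'   only)? Defaults to `TRUE` for the distance/kernel families KNN and
#'   SVM, `FALSE` for the scale-invariant GB trees.
#' @param gap_tol,plateau_tol Learning-curve fit-diagnosis tolerances (see
#'   [diagnose_fit()]).
#' @return A list of class `model_config`.
#' @export
model_config <- function(family = c("KNN", "SVM", "GB"), grid = NULL,
                         cv_folds = 10L, seed = 22L,
                         standardize = NULL, gap_tol = 0.05,
                         plateau_tol = 0.01) {
  family <- match.arg(family)
  grid <- grid %||% default_grid(family)
  if (!length(grid) || any(!vapply(grid, length, integer(1))))
    stopf("hyper-parameter grid must be non-empty")
  structure(list(family = family, grid = grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed),
                 standardize = standardize %||% (family != "GB"),
                 gap_tol = gap_tol, plateau_tol = plateau_tol),
            class = "model_config")
}

# Deterministic stratified fold assignment: within each class, indices are
# shuffled under the seed and dealt round-robin over the folds.
stratified_folds <- function(y, k, seed) {
  counts <- table(y)
  small <- counts[counts < k]
  if (length(small))
    stopf("stratification error: class(es) %s have fewer rows than cv_folds = %d",
          paste(names(small), collapse = ", "), k, class = "gaitstager_strat")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

scale_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
scale_apply <- function(x, sc) sweep(sweep(x, 2L, sc$center), 2L, sc$scale, "/")

# ---- per-family fit / predict -------------------------------------------

fit_one <- function(x, y, family, params, seed = 22L) {
  if (family == "KNN") {
    list(kind = "KNN", x = x, y = y, params = params)
  } else if (family == "SVM") {
    gamma <- params$gamma %||% "scale"
    if (identical(gamma, "scale")) {
      v <- stats::var(as.vector(x))
      gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
    }
    fit <- e1071::svm(x = x, y = y, type = "C-classification",
                      kernel = if (params$kernel == "rbf") "radial" else "linear",
                      cost = params$C, gamma = gamma, scale = FALSE)
    list(kind = "SVM", fit = fit, levels = levels(y))
  } else if (family == "GB") {
    k <- nlevels(y)
    fit <- xgboost::xgb.train(
      data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L),
      nrounds = params$n_estimators,
      params = list(objective = "multi:softprob", num_class = k,
                    max_depth = 3, eta = 0.1, nthread = 1,
                    seed = seed),
      verbose = 0)
    list(kind = "GB", fit = fit, levels = levels(y), k = k)
  } else stopf("unknown model family '%s'", family)
}

# Returns list(class = factor predictions, score = rows x classes matrix).
# Scores are class-membership strengths used for one-vs-rest ROC: KNN
# neighbour-vote fractions, SVM sums of signed pairwise decision values,
# GB softmax probabilities.
dist_mat <- function(metric, a, b) {
  if (metric == "manhattan") {
    out <- matrix(0, nrow(a), nrow(b))
    for (j in seq_len(ncol(a)))
      out <- out + abs(outer(a[, j], b[, j], "-"))
    out
  } else {
    # euclidean; minkowski uses the conventional default power p = 2 and
    # therefore coincides with euclidean
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    sqrt(pmax(d2, 0))
  }
}

# k-nearest-neighbour labels and distances: for each query row the ordered
# nearest `k` training indices (stable ties), their labels and distances.
knn_neighbors <- function(d, y_int, k) {
  ord <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  if (k == 1L) ord <- matrix(ord, ncol = 1L)
  idx <- cbind(rep(seq_len(nrow(d)), k), as.vector(ord))
  list(labels = matrix(y_int[ord], nrow(d), k),
       dists = matrix(d[idx], nrow(d), k))
}

# Vote scores over K classes from neighbour labels/distances.
knn_scores <- function(nb, k, weights, K) {
  L <- nb$labels[, seq_len(k), drop = FALSE]
  W <- if (identical(weights, "distance"))
    1 / pmax(nb$dists[, seq_len(k), drop = FALSE], 1e-12)
  else matrix(1, nrow(L), k)
  score <- matrix(0, nrow(L), K)
  for (cl in seq_len(K)) score[, cl] <- rowSums((L == cl) * W)
  score / rowSums(score)
}

predict_one <- function(fitted, x) {
  if (fitted$kind == "KNN") {
    tr <- fitted$x; y <- fitted$y; p <- fitted$params
    k <- min(p$n_neighbors, nrow(tr))
    d <- dist_mat(p$metric, x, tr)
    K <- nlevels(y)
    nb <- knn_neighbors(d, as.integer(y), k)
    score <- knn_scores(nb, k, p$weights, K)
    colnames(score) <- levels(y)
    # ties broken toward the lowest severity stage (first factor level)
    cls <- factor(levels(y)[max.col(score, ties.method = "first")],
                  levels = levels(y))
    list(class = cls, score = score)
  } else if (fitted$kind == "SVM") {
    pr <- stats::predict(fitted$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    lv <- fitted$levels
    score <- matrix(0, nrow(x), length(lv), dimnames = list(NULL, lv))
    for (cn in colnames(dv)) {
      pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
      score[, pair[1]] <- score[, pair[1]] + dv[, cn]
      score[, pair[2]] <- score[, pair[2]] - dv[, cn]
    }
    list(class = factor(as.character(pr), levels = lv), score = score)
  } else {
    prob <- stats::predict(fitted$fit, xgboost::xgb.DMatrix(x))
    # softprob predictions arrive row-major; reshape when returned flat
    score <- if (is.matrix(prob)) prob
             else matrix(prob, nrow(x), fitted$k, byrow = TRUE)
    dimnames(score) <- list(NULL, fitted$levels)
    cls <- factor(fitted$levels[max.col(score, ties.method = "first")],
                  levels = fitted$levels)
    list(class = cls, score = score)
  }
}

prep_xy <- function(table) {
  feats <- gait_feature_names()
  missing_cols <- setdiff(feats, names(table))
  if (length(missing_cols))
    stopf("feature table missing column(s): %s", paste(missing_cols, collapse = ", "),
          class = "gaitstager_schema")
  x <- as.matrix(table[, feats])
  y <- if ("stage" %in% names(table))
    droplevels(factor(table$stage, levels = stage_levels())) else NULL
  list(x = x, y = y)
}

grid_rows <- function(grid) {
  df <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

cv_accuracy <- function(x, y, fold, family, params, standardize, seed) {
  k <- max(fold)
  vapply(seq_len(k), function(f) {
    tr <- fold != f; te <- fold == f
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (standardize) {
      sc <- scale_fit(xtr)
      xtr <- scale_apply(xtr, sc); xte <- scale_apply(xte, sc)
    }
    fit <- fit_one(xtr, y[tr], family, params, seed)
    mean(predict_one(fit, xte)$class == y[te])
  }, numeric(1))
}

#' Grid-search a stage classifier under stratified cross-validation
#'
#' Scores every hyper-parameter combination of the configured grid by mean
#' stratified k-fold cross-validation accuracy, picks the best (ties go to
#' the earliest grid entry) and refits it on all rows. Deterministic given
#' the configuration seed.
#'
#' @param table Labeled feature `data.frame` (columns of
#'   [gait_feature_names()] plus `stage`); every class needs at least
#'   `cv_folds` rows.
#' @param cfg A [model_config()].
#' @return An object of class `gait_model`: the refit classifier plus
#'   `best_params`, `fold_scores` (per-fold CV accuracy of the winner),
#'   `cv_accuracy` (their mean) and `cv_results` (all grid points).
#' @export
grid_search_train <- function(table, cfg) {
  stopifnot(inherits(cfg, "model_config"))
  d <- prep_xy(table)
  if (is.null(d$y)) stopf("training table must carry a 'stage' column")
  fold <- stratified_folds(d$y, cfg$cv_folds, cfg$seed)
  rows <- grid_rows(cfg$grid)
  res <- lapply(rows, function(p)
    cv_accuracy(d$x, d$y, fold, cfg$family, p, cfg$standardize, cfg$seed))
  means <- vapply(res, mean, numeric(1))
  best <- which.max(means)            # first maximum on ties
  x_all <- d$x
  sc <- NULL
  if (cfg$standardize) {
    sc <- scale_fit(x_all)
    x_all <- scale_apply(x_all, sc)
  }
  fit <- fit_one(x_all, d$y, cfg$family, rows[[best]], cfg$seed)
  structure(list(family = cfg$family, best_params = rows[[best]],
                 fold_scores = res[[best]], cv_accuracy = means[best],
                 cv_results = data.frame(
                   expand.grid(cfg$grid, stringsAsFactors = FALSE),
                   mean_cv_accuracy = means),
                 fit = fit, scaling = sc, cfg = cfg,
                 levels = levels(d$y), feature_names = gait_feature_names()),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model %s> CV accuracy %.3f; best: %s\n", x$family,
              x$cv_accuracy,
              paste(names(x$best_params), unlist(x$best_params),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Predict stages or class scores from a fitted model
#'
#' @param object A `gait_model`.
#' @param newdata Feature `data.frame` or matrix with the canonical
#'   feature columns.
#' @param type `"class"` for stage labels, `"score"` for the per-class
#'   score matrix.
#' @param ... Unused.
#' @return Factor of stages, or a numeric score matrix.
#' @export
predict.gait_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else prep_xy(newdata)$x
  if (!is.null(object$scaling)) x <- scale_apply(x, object$scaling)
  pr <- predict_one(object$fit, x)
  if (type == "class") pr$class else pr$score
}

#' Learning curve under stratified cross-validation
#'
#' For each training-set fraction, trains the given hyper-parameter
#' combination on a stratified subset of each fold's training part and
#' records the training accuracy on that subset and the validation accuracy
#' on the held-out fold, averaged over folds.
#'
#' @param table Labeled feature `data.frame`.
#' @param cfg A [model_config()].
#' @param fractions Increasing training-size fractions in (0, 1\]
#'   (default ten steps 0.1-1.0).
#' @param params Single hyper-parameter combination (named list); defaults
#'   to the first value of each grid entry.
#' @return An object of class `learning_curve` with `train_sizes`,
#'   `train_scores`, `val_scores`, `val_score_sd` and the chance level.
#' @export
learning_curve <- function(table, cfg, fractions = seq(0.1, 1, by = 0.1),
                           params = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (any(diff(fractions) <= 0) || any(fractions <= 0 | fractions > 1))
    stopf("fractions must be increasing values in (0, 1]")
  params <- params %||% lapply(cfg$grid, `[`, 1L)
  d <- prep_xy(table)
  if (is.null(d$y)) stopf("learning_curve needs a labeled table")
  fold <- stratified_folds(d$y, cfg$cv_folds, cfg$seed)
  k <- cfg$cv_folds

  # one fixed shuffled order per class so subsets are nested across fractions
  class_order <- with_seed(cfg$seed + 1L, lapply(levels(d$y), function(cl) {
    idx <- which(d$y == cl)
    idx[sample.int(length(idx))]
  }))

  nf <- length(fractions)
  tr_m <- matrix(NA_real_, k, nf); va_m <- matrix(NA_real_, k, nf)
  sz_m <- matrix(NA_real_, k, nf)
  for (f in seq_len(k)) {
    tr_pool <- which(fold != f); te <- which(fold == f)
    for (j in seq_len(nf)) {
      sub <- unlist(lapply(class_order, function(idx) {
        avail <- idx[idx %in% tr_pool]
        avail[seq_len(max(1L, ceiling(fractions[j] * length(avail))))]
      }))
      xtr <- d$x[sub, , drop = FALSE]; ytr <- d$y[sub]
      xte <- d$x[te, , drop = FALSE]
      if (cfg$standardize) {
        sc <- scale_fit(xtr)
        xtr <- scale_apply(xtr, sc); xte2 <- scale_apply(xte, sc)
        xsub <- xtr
      } else { xte2 <- xte; xsub <- xtr }
      fit <- fit_one(xtr, ytr, cfg$family, params, cfg$seed)
      tr_m[f, j] <- mean(predict_one(fit, xsub)$class == ytr)
      va_m[f, j] <- mean(predict_one(fit, xte2)$class == d$y[te])
      sz_m[f, j] <- length(sub)
    }
  }
  structure(list(train_sizes = round(colMeans(sz_m)),
                 train_scores = colMeans(tr_m),
                 val_scores = colMeans(va_m),
                 val_score_sd = apply(va_m, 2L, stats::sd),
                 fractions = fractions,
                 chance = 1 / nlevels(d$y),
                 family = cfg$family, params = params),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve %s> sizes %s; final train %.3f / val %.3f\n",
              x$family, paste(x$train_sizes, collapse = ","),
              x$train_scores[length(x$train_scores)],
              x$val_scores[length(x$val_scores)]))
  invisible(x)
}

#' Plot a learning curve
#'
#' @param x A `learning_curve`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.learning_curve <- function(x, ...) {
  graphics::matplot(x$train_sizes, cbind(x$train_scores, x$val_scores),
                    type = "b", pch = c(1, 2), lty = 1,
                    col = c("steelblue", "firebrick"),
                    xlab = "training examples", ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), pch = c(1, 2), lty = 1)
  invisible(x)
}

#' Diagnose a learning curve as good fit, overfit or underfit
#'
#' A curve is a good fit when the final train-validation gap is within
#' `gap_tol`, validation accuracy has plateaued (improvement over the last
#' third of the size axis within `plateau_tol`) and the final validation
#' accuracy is above chance. A gap beyond `gap_tol` is an overfit; a final
#' validation accuracy within 0.05 of chance -- or a curve still climbing --
#' is an underfit (more data or capacity needed).
#'
#' @param lc A [learning_curve()].
#' @param gap_tol Tolerated final train-validation accuracy gap
#'   (default 0.05).
#' @param plateau_tol Tolerated validation improvement over the last third
#'   (default 0.01).
#' @return An object of class `fit_diagnosis`: `final_gap`,
#'   `val_plateau_delta`, `verdict` and the thresholds used.
#' @export
diagnose_fit <- function(lc, gap_tol = 0.05, plateau_tol = 0.01) {
  stopifnot(inherits(lc, "learning_curve"))
  k <- length(lc$val_scores)
  if (k < 4L) stopf("diagnosis needs at least 4 training sizes")
  final_gap <- lc$train_scores[k] - lc$val_scores[k]
  i0 <- ceiling(2 * k / 3)
  plateau_delta <- lc$val_scores[k] - lc$val_scores[i0]
  verdict <- if (final_gap > gap_tol) "overfit"
    else if (lc$val_scores[k] <= lc$chance + 0.05) "underfit"
    else if (plateau_delta <= plateau_tol && lc$val_scores[k] > lc$chance) "good_fit"
    else "underfit"   # validation still climbing: more data needed
  structure(list(final_gap = final_gap, val_plateau_delta = plateau_delta,
                 verdict = verdict, gap_tol = gap_tol,
                 plateau_tol = plateau_tol, chance = lc$chance),
            class = "fit_diagnosis")
}

#' @export
print.fit_diagnosis <- function(x, ...) {
  cat(sprintf("<fit_diagnosis> %s (gap %.3f <= %.3f?; plateau %.3f <= %.3f?)\n",
              x$verdict, x$final_gap, x$gap_tol, x$val_plateau_delta,
              x$plateau_tol))
  invisible(x)
}

# Learning curves for every KNN grid combination at once. The expensive
# parts (fold/fraction subsetting, scaling, distance matrices, neighbour
# sorting) are shared across combinations, which only differ in how the
# same sorted neighbour lists are voted on. Reproduces learning_curve()
# exactly for each combination.
knn_curve_grid <- function(table, cfg, fractions = seq(0.1, 1, by = 0.1)) {
  d <- prep_xy(table)
  fold <- stratified_folds(d$y, cfg$cv_folds, cfg$seed)
  combos <- grid_rows(cfg$grid)
  K <- nlevels(d$y)
  kmax <- max(vapply(combos, function(p) p$n_neighbors, numeric(1)))
  metrics <- unique(vapply(combos, function(p) p$metric, character(1)))
  # minkowski (p = 2) shares the euclidean distance matrix
  met_key <- function(m) if (m == "minkowski") "euclidean" else m

  class_order <- with_seed(cfg$seed + 1L, lapply(levels(d$y), function(cl) {
    idx <- which(d$y == cl)
    idx[sample.int(length(idx))]
  }))

  nf <- length(fractions); k10 <- cfg$cv_folds; nc <- length(combos)
  tr_a <- array(NA_real_, c(nc, k10, nf)); va_a <- array(NA_real_, c(nc, k10, nf))
  sz_m <- matrix(NA_real_, k10, nf)
  for (f in seq_len(k10)) {
    tr_pool <- which(fold != f); te <- which(fold == f)
    for (j in seq_len(nf)) {
      sub <- unlist(lapply(class_order, function(idx) {
        avail <- idx[idx %in% tr_pool]
        avail[seq_len(max(1L, ceiling(fractions[j] * length(avail))))]
      }))
      sz_m[f, j] <- length(sub)
      xtr <- d$x[sub, , drop = FALSE]; xte <- d$x[te, , drop = FALSE]
      if (cfg$standardize) {
        sc <- scale_fit(xtr)
        xtr <- scale_apply(xtr, sc); xte <- scale_apply(xte, sc)
      }
      y_int <- as.integer(d$y[sub])
      km <- min(kmax, nrow(xtr))
      for (m in unique(vapply(metrics, met_key, character(1)))) {
        nb_tr <- knn_neighbors(dist_mat(m, xtr, xtr), y_int, km)
        nb_te <- knn_neighbors(dist_mat(m, xte, xtr), y_int, km)
        for (ci in seq_len(nc)) {
          p <- combos[[ci]]
          if (met_key(p$metric) != m) next
          kk <- min(p$n_neighbors, nrow(xtr))
          pr_tr <- max.col(knn_scores(nb_tr, kk, p$weights, K),
                           ties.method = "first")
          pr_te <- max.col(knn_scores(nb_te, kk, p$weights, K),
                           ties.method = "first")
          tr_a[ci, f, j] <- mean(pr_tr == y_int)
          va_a[ci, f, j] <- mean(pr_te == as.integer(d$y[te]))
        }
      }
    }
  }
  lapply(seq_len(nc), function(ci) {
    va <- va_a[ci, , , drop = TRUE]
    structure(list(train_sizes = round(colMeans(sz_m)),
                   train_scores = colMeans(tr_a[ci, , , drop = TRUE]),
                   val_scores = colMeans(va),
                   val_score_sd = apply(va, 2L, stats::sd),
                   fractions = fractions, chance = 1 / K,
                   family = cfg$family, params = combos[[ci]]),
              class = "learning_curve")
  })
}

#' Screen a hyper-parameter grid by learning-curve fit
#'
#' Scores every grid combination by stratified-CV accuracy, obtains each
#' combination's learning curve, diagnoses it, and chooses -- among the
#' combinations whose curves show a good fit -- the one with the highest
#' CV accuracy. For KNN all curves are computed through a shared fast
#' path; for the other families combinations are screened in order of
#' decreasing CV accuracy, stopping at the first good fit (which is by
#' construction the chosen one).
#'
#' @param table Labeled feature `data.frame`.
#' @param cfg A [model_config()].
#' @param fractions Learning-curve fractions.
#' @return List with `chosen` (`params`, `cv_accuracy`, `learning_curve`,
#'   `diagnosis`; `NULL` when no combination passes) and `combos`
#'   (per-combination records: params, CV accuracy, verdict or NA when not
#'   screened).
#' @export
screen_good_fit <- function(table, cfg, fractions = seq(0.1, 1, by = 0.1)) {
  stopifnot(inherits(cfg, "model_config"))
  d <- prep_xy(table)
  if (is.null(d$y)) stopf("screening needs a labeled table")
  fold <- stratified_folds(d$y, cfg$cv_folds, cfg$seed)
  rows <- grid_rows(cfg$grid)
  means <- vapply(rows, function(p)
    mean(cv_accuracy(d$x, d$y, fold, cfg$family, p, cfg$standardize, cfg$seed)),
    numeric(1))

  verdicts <- rep(NA_character_, length(rows))
  curves <- vector("list", length(rows))
  diags <- vector("list", length(rows))
  if (cfg$family == "KNN") {
    curves <- knn_curve_grid(table, cfg, fractions)
    for (i in seq_along(rows)) {
      diags[[i]] <- diagnose_fit(curves[[i]], cfg$gap_tol, cfg$plateau_tol)
      verdicts[i] <- diags[[i]]$verdict
    }
    good <- which(verdicts == "good_fit")
    best <- if (length(good)) good[which.max(means[good])] else NA_integer_
  } else {
    best <- NA_integer_
    for (i in order(-means, seq_along(means))) {
      curves[[i]] <- learning_curve(table, cfg, fractions, rows[[i]])
      diags[[i]] <- diagnose_fit(curves[[i]], cfg$gap_tol, cfg$plateau_tol)
      verdicts[i] <- diags[[i]]$verdict
      if (verdicts[i] == "good_fit") { best <- i; break }
    }
  }
  chosen <- if (!is.na(best))
    list(params = rows[[best]], cv_accuracy = means[best],
         learning_curve = curves[[best]], diagnosis = diags[[best]])
  combos <- lapply(seq_along(rows), function(i)
    list(params = rows[[i]], cv_accuracy = means[i], verdict = verdicts[i]))
  list(chosen = chosen, combos = combos)
}

#' Select, per family, the smallest synthetic dataset giving a good fit
#'
#' For each model family, scans the candidate numbers of linear
#' combinations in ascending order; for each candidate it builds the
#' synthetic dataset and screens the family's hyper-parameter grid by
#' learning-curve fit ([screen_good_fit()]). The first candidate with a
#' good-fit combination is chosen (all candidates are recorded). Training
#' failures at a candidate are recorded and scanning continues.
#'
#' @param exemplars Output of [prepare_exemplars()] (elements `p` and `n`).
#' @param families Subset of `c("KNN", "SVM", "GB")`.
#' @param candidate_counts Numbers of linear combinations to try,
#'   default `c(20, 40, 60, 80, 100, 200, 250)`.
#' @param peak_cfg Extremum-detection settings for feature extraction.
#' @param cv_folds,seed,gap_tol,plateau_tol Passed to [model_config()] and
#'   [diagnose_fit()].
#' @param fractions Learning-curve fractions.
#' @return Named list per family: `chosen` (`n_combinations`,
#'   `best_params`, `cv_accuracy`, `diagnosis`; `NULL` when no candidate
#'   passes) and `candidates` (per-count records).
#' @export
select_model_and_dataset <- function(exemplars, families = c("KNN", "SVM", "GB"),
                                     candidate_counts = c(20, 40, 60, 80, 100, 200, 250),
                                     peak_cfg = list(), cv_folds = 10L,
                                     seed = 22L, gap_tol = 0.05,
                                     plateau_tol = 0.01,
                                     fractions = seq(0.1, 1, by = 0.1)) {
  if (!length(candidate_counts)) stopf("candidate_counts must be non-empty")
  candidate_counts <- sort(candidate_counts)
  datasets <- lapply(candidate_counts, function(n)
    build_synthetic_dataset(exemplars$p, exemplars$n, n, peak_cfg))
  out <- lapply(families, function(fam) {
    cfg <- model_config(fam, cv_folds = cv_folds, seed = seed,
                        gap_tol = gap_tol, plateau_tol = plateau_tol)
    records <- list(); chosen <- NULL
    for (i in seq_along(candidate_counts)) {
      n <- candidate_counts[i]
      rec <- tryCatch({
        sc <- screen_good_fit(datasets[[i]], cfg, fractions)
        list(n_combinations = n,
             best_params = sc$chosen$params,
             cv_accuracy = sc$chosen$cv_accuracy %||% NA_real_,
             diagnosis = sc$chosen$diagnosis, combos = sc$combos,
             error = NULL)
      }, error = function(e) list(n_combinations = n, best_params = NULL,
                                  cv_accuracy = NA_real_, diagnosis = NULL,
                                  combos = NULL, error = conditionMessage(e)))
      records[[as.character(n)]] <- rec
      if (is.null(chosen) && is.null(rec$error) &&
          !is.null(rec$diagnosis) &&
          rec$diagnosis$verdict == "good_fit") chosen <- rec
    }
    list(chosen = chosen, candidates = records)
  })
  stats::setNames(out, families)
}

#' Predict stages for unseen gait features, with per-row voting
#'
#' Every feature row receives a stage prediction; the summary counts the
#' votes per stage and reports the modal stage (ties resolved toward the
#' lowest severity).
#'
#' @param model A `gait_model`.
#' @param table Unlabeled feature `data.frame` with the canonical columns.
#' @return List with `per_row` (factor of stages), `counts` (named vote
#'   counts over all four stages) and `modal` (the winning stage).
#' @export
predict_stage <- function(model, table) {
  if (nrow(table) == 0L) stopf("empty feature table", class = "gaitstager_empty")
  pred <- stats::predict(model, table)
  stage_votes(pred)
}

#' Vote-count summary of per-row stage predictions
#'
#' @param pred Vector or factor of stage predictions.
#' @return List with `per_row`, `counts` (over all four stages) and
#'   `modal` (ties resolved toward the lowest severity).
#' @export
stage_votes <- function(pred) {
  pred <- factor(pred, levels = stage_levels())
  counts <- table(pred)
  modal <- names(counts)[which.max(counts)]   # first max = lowest stage on ties
  list(per_row = pred, counts = counts, modal = modal)
}

#' Persist a fitted stage classifier
#'
#' Writes a versioned RDS archive. The gradient-boosting booster is stored
#' in its raw serialized form so the archive reloads across sessions.
#'
#' @param model A `gait_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_gait_model <- function(model, path) {
  stopifnot(inherits(model, "gait_model"))
  obj <- unclass(model)
  if (obj$fit$kind == "GB") {
    obj$fit$raw <- xgboost::xgb.save.raw(obj$fit$fit)
    obj$fit$fit <- NULL
  }
  saveRDS(list(format = "gaitstager_model", version = 1L, model = obj), path)
  invisible(path)
}

#' Load a persisted stage classifier
#'
#' @param path Archive written by [save_gait_model()].
#' @return The restored `gait_model`.
#' @export
load_gait_model <- function(path) {
  arc <- readRDS(path)
  if (!identical(arc$format, "gaitstager_model"))
    stopf("'%s' is not a gaitstager model archive", path)
  obj <- arc$model
  if (obj$fit$kind == "GB") {
    obj$fit$fit <- xgboost::xgb.load.raw(obj$fit$raw)
    obj$fit$raw <- NULL
  }
  structure(obj, class = "gait_model")
}
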