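# Small labeled tables for classifier tests.
separable_table <- function(n_per = 30, classes = c("I", "II"), shift = 10,
                            seed = 5) {
  set.seed(seed)
  rows <- lapply(seq_along(classes), function(k) {
    m <- matrix(rnorm(n_per * 7, mean = shift * k), n_per, 7)
    df <- as.data.frame(m)
    names(df) <- gait_feature_names()
    df$stage <- classes[k]
    df
  })
  out <- do.call(rbind, rows)
  out$stage <- factor(out$stage, levels = stage_levels())
  out
}

noise_table <- function(n = 200, seed = 11) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n * 7), n, 7))
  names(df) <- gait_feature_names()
  df$stage <- factor(rep(stage_levels(), length.out = n), levels = stage_levels())
  df
}

test_that("default grids match the canonical hyper-parameter lists", {
  g <- default_grid("KNN")
  expect_equal(g$n_neighbors, c(1, 3, 5, 7, 9, 11, 13, 15))
  expect_setequal(g$metric, c("euclidean", "manhattan", "minkowski"))
  expect_setequal(g$weights, c("uniform", "distance"))
  expect_equal(default_grid("SVM")$C, c(0.01, 0.1, 1, 10, 100))
  expect_equal(default_grid("GB")$n_estimators, c(1, 2, 5, 20, 50, 100))
})

test_that("grid search is exhaustive, deterministic and perfect on separated classes", {
  tab <- separable_table()
  cfg <- model_config("KNN", grid = list(n_neighbors = c(1, 3),
                                         metric = "euclidean",
                                         weights = "uniform"),
                      cv_folds = 5)
  gs <- grid_search_train(tab, cfg)
  expect_equal(gs$cv_accuracy, 1)
  expect_equal(mean(gs$fold_scores), gs$cv_accuracy)
  # exhaustiveness: the winner's score is the max over all grid points
  expect_equal(gs$cv_accuracy, max(gs$cv_results$mean_cv_accuracy))
  expect_equal(nrow(gs$cv_results), 2)
  gs2 <- grid_search_train(tab, cfg)
  expect_identical(gs2$best_params, gs$best_params)
  expect_identical(gs2$fold_scores, gs$fold_scores)
  # stratification guard
  tiny <- tab[c(1:20, 31:33), ]
  expect_error(grid_search_train(tiny, model_config("KNN", cv_folds = 5)),
               class = "gaitstager_strat")
})

test_that("pure-noise labels score at chance for all three families", {
  tab <- noise_table()
  for (fam in c("KNN", "SVM", "GB")) {
    grid <- switch(fam,
      KNN = list(n_neighbors = 5, metric = "euclidean", weights = "uniform"),
      SVM = list(C = 1, kernel = "rbf", gamma = "scale"),
      GB = list(n_estimators = 5))
    gs <- grid_search_train(tab, model_config(fam, grid = grid, cv_folds = 5))
    expect_gt(gs$cv_accuracy, 0.25 - 0.1)
    expect_lt(gs$cv_accuracy, 0.25 + 0.1)
  }
})

test_that("all three families separate the synthetic stages well", {
  ex <- sim_exemplars()
  tab <- build_synthetic_dataset(ex$p, ex$n, 40)
  for (fam in c("SVM", "GB")) {
    gs <- grid_search_train(tab, model_config(fam))
    expect_gt(gs$cv_accuracy, 0.7)
    pred <- predict(gs, tab)
    expect_gt(mean(pred == tab$stage), 0.7)
    sc <- predict(gs, tab, type = "score")
    expect_equal(dim(sc), c(nrow(tab), nlevels(droplevels(tab$stage))))
  }
})

test_that("learning curve sizes follow fold arithmetic and scores track separability", {
  tab <- separable_table(n_per = 50)
  cfg <- model_config("KNN", grid = list(n_neighbors = 3, metric = "euclidean",
                                         weights = "uniform"), cv_folds = 10)
  lc <- learning_curve(tab, cfg, fractions = c(0.5, 1.0))
  expect_equal(length(lc$train_sizes), 2)
  # 100 rows, 10-fold: training pool 90, so sizes ~= 45 and 90
  expect_equal(lc$train_sizes, c(45, 90), tolerance = 0.05)
  expect_true(all(lc$val_scores > 0.99))
  lcn <- learning_curve(noise_table(), model_config(
    "KNN", grid = list(n_neighbors = 5, metric = "euclidean", weights = "uniform")),
    fractions = seq(0.25, 1, 0.25))
  expect_true(all(abs(lcn$val_scores - 0.25) < 0.12))
})

test_that("fit diagnosis applies the gap/plateau/chance rule", {
  mk <- function(tr, va, chance = 0.25) {
    structure(list(train_sizes = seq_along(tr) * 10, train_scores = tr,
                   val_scores = va, val_score_sd = rep(0, length(tr)),
                   fractions = seq_along(tr) / length(tr), chance = chance,
                   family = "KNN", params = list()),
              class = "learning_curve")
  }
  expect_equal(diagnose_fit(mk(c(1, 1, 1, 1), c(0.5, 0.55, 0.6, 0.6)))$verdict,
               "overfit")
  d <- diagnose_fit(mk(c(0.96, 0.95, 0.95, 0.95), c(0.80, 0.90, 0.94, 0.945)))
  expect_equal(d$verdict, "good_fit")
  expect_equal(d$final_gap, 0.95 - 0.945)
  expect_equal(diagnose_fit(mk(rep(0.25, 4), rep(0.25, 4)))$verdict, "underfit")
  # brute-force application of the same rule on random tabulated curves
  set.seed(3)
  for (i in 1:25) {
    tr <- sort(runif(6, 0.5, 1)); va <- sort(runif(6, 0.2, 1))
    lc <- mk(tr, va)
    d <- diagnose_fit(lc, gap_tol = 0.05, plateau_tol = 0.01)
    gap <- tr[6] - va[6]
    plat <- va[6] - va[ceiling(2 * 6 / 3)]
    expected <- if (gap > 0.05) "overfit"
      else if (va[6] <= 0.30) "underfit"
      else if (plat <= 0.01 && va[6] > 0.25) "good_fit" else "underfit"
    expect_equal(d$verdict, expected)
  }
})

test_that("model selection screens hyper-parameter combos by good fit", {
  tab <- separable_table(n_per = 60, classes = c("I", "II", "III"), shift = 4)
  cfg_grid <- list(n_neighbors = c(1, 5), metric = "euclidean",
                   weights = "uniform")
  sel <- screen_good_fit(tab, model_config("KNN", grid = cfg_grid))
  expect_true(!is.null(sel$chosen))
  expect_equal(sel$chosen$diagnosis$verdict, "good_fit")
  # noise labels never produce a good fit
  seln <- screen_good_fit(noise_table(), model_config(
    "KNN", grid = cfg_grid))
  expect_null(seln$chosen)
  expect_error(select_model_and_dataset(sim_exemplars(), "KNN",
                                        candidate_counts = c()),
               "non-empty")
})

test_that("per-row voting counts stages and reports the modal stage", {
  tab <- separable_table(n_per = 20)
  gs <- grid_search_train(tab, model_config(
    "KNN", grid = list(n_neighbors = 1, metric = "euclidean",
                       weights = "uniform"), cv_folds = 5))
  # k = 1 on a training row returns that row's own label
  ps <- predict_stage(gs, tab[1, ])
  expect_equal(as.character(ps$per_row), "I")
  ps2 <- predict_stage(gs, tab[, gait_feature_names()])
  expect_equal(unname(as.integer(ps2$counts)), c(20, 20, 0, 0))
  expect_equal(ps2$modal, "I")  # tie resolved toward the lowest stage
  expect_error(predict_stage(gs, tab[0, ]), class = "gaitstager_empty")
})

test_that("models survive a save/load round trip", {
  tab <- separable_table(n_per = 15, classes = c("I", "III"))
  for (fam in c("KNN", "SVM", "GB")) {
    grid <- switch(fam,
      KNN = list(n_neighbors = 3, metric = "euclidean", weights = "uniform"),
      SVM = list(C = 1, kernel = "linear", gamma = "scale"),
      GB = list(n_estimators = 5))
    gs <- grid_search_train(tab, model_config(fam, grid = grid, cv_folds = 5))
    path <- withr::local_tempfile(fileext = ".rds")
    save_gait_model(gs, path)
    m2 <- load_gait_model(path)
    expect_identical(predict(m2, tab), predict(gs, tab))
  }
})
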