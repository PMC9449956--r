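# two well-separated Gaussian blobs in 2 dims
blob_data <- function(n = 100, sep = 10, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n), n / 2, 2),
             matrix(rnorm(n, mean = sep), n / 2, 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c("a", "b"), each = n / 2))
}

test_that("default grids span the full published ranges", {
  g <- default_svm_grid()
  expect_equal(length(g$C), 12)
  expect_equal(length(g$gamma), 7)
  expect_equal(range(g$C), c(1e-3, 1e8))
  expect_equal(range(g$gamma), c(1e-3, 1e3))
  # exhaustive grid has 84 cells
  d <- blob_data()
  gs <- grid_search_svm(d$x, d$y, folds = 5, seed = 1)
  expect_equal(nrow(gs$grid), 84)
})

test_that("grid search finds perfect separation on separable blobs", {
  d <- blob_data(n = 100, sep = 10)
  gs <- grid_search_svm(d$x, d$y, C_grid = c(0.1, 1, 10),
                        gamma_grid = c(0.01, 0.1, 1), folds = 5, seed = 2)
  expect_equal(gs$cv_accuracy, 1.0)
  expect_true(any(gs$grid$accuracy == 1.0))
  # best cell attains the grid maximum
  expect_equal(gs$cv_accuracy, max(gs$grid$accuracy))
})

test_that("grid search is invariant to cell order and row duplication", {
  d <- blob_data(n = 60, sep = 6, seed = 9)
  gs1 <- grid_search_svm(d$x, d$y, C_grid = c(10, 0.1, 1),
                         gamma_grid = c(1, 0.01), folds = 3, seed = 5)
  gs2 <- grid_search_svm(d$x, d$y, C_grid = c(0.1, 1, 10),
                         gamma_grid = c(0.01, 1), folds = 3, seed = 5)
  expect_equal(gs1$best_C, gs2$best_C)
  expect_equal(gs1$best_gamma, gs2$best_gamma)
  expect_equal(gs1$cv_accuracy, gs2$cv_accuracy)

  dup <- grid_search_svm(rbind(d$x, d$x), c(d$y, d$y),
                         C_grid = c(0.1, 1, 10), gamma_grid = c(0.01, 1),
                         folds = 3, seed = 5)
  expect_equal(dup$best_C, gs2$best_C)
  expect_equal(dup$best_gamma, gs2$best_gamma)
})

test_that("grid search rejects degenerate input", {
  d <- blob_data()
  expect_error(grid_search_svm(d$x, rep("a", nrow(d$x))),
               "at least two classes")
  expect_error(grid_search_svm(d$x[1:52, ], d$y[1:52], folds = 5),
               "stratified")
})

test_that("movement classifiers enforce the feature arity", {
  feats <- small_features()
  w9 <- movement_feature_subset(feats, "whistle")
  expect_equal(ncol(w9), 9)
  clf <- train_movement_classifier("whistle", w9, feats$label,
                                   C = 10, gamma = 0.1, seed = 3)
  expect_s3_class(clf, "fp_movement_classifier")
  expect_error(train_movement_classifier("whistle", w9[, 1:8], feats$label),
               "expects 9 feature columns")
  expect_error(train_movement_classifier("smiling", w9, feats$label),
               "expects 8 feature columns")
  expect_error(train_movement_classifier("whistle", w9,
                                         rep("N", nrow(w9))),
               "single class")
})

test_that("refitting with the same data and seed reproduces predictions", {
  feats <- small_features()
  x <- movement_feature_subset(feats, "smiling")
  probe <- x[1:20, ]
  for (kind in c("svm_rbf", "knn", "random_forest")) {
    c1 <- train_movement_classifier("smiling", x, feats$label, kind = kind,
                                    seed = 42)
    c2 <- train_movement_classifier("smiling", x, feats$label, kind = kind,
                                    seed = 42)
    expect_identical(predict(c1, probe), predict(c2, probe))
    expect_identical(predict(c1, probe, type = "prob"),
                     predict(c2, probe, type = "prob"))
  }
})

test_that("probability vectors sum to one", {
  feats <- small_features()
  x <- movement_feature_subset(feats, "eye_closure")
  clf <- train_movement_classifier("eye_closure", x, feats$label, seed = 2)
  p <- predict(clf, x[1:15, ], type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, 15), tolerance = 1e-9)
  expect_setequal(colnames(p), unique(feats$label))
})

test_that("threshold moving demotes only weak normal-class wins", {
  expect_equal(predict_with_threshold(
    c(N = 0.38, R_MO = 0.30, L_MI = 0.20, R_MI = 0.07, R_S = 0.05)),
    "R_MO")
  expect_equal(predict_with_threshold(
    c(N = 0.41, R_MO = 0.39, L_MI = 0.10, R_MI = 0.05, R_S = 0.05)),
    "N")
  expect_equal(predict_with_threshold(
    c(R_S = 0.35, N = 0.30, L_MI = 0.15, R_MI = 0.1, R_MO = 0.1)),
    "R_S")
  expect_error(predict_with_threshold(numeric(0)), "empty")

  # identity whenever N is not argmax or P(N) >= threshold
  set.seed(77)
  for (i in 1:200) {
    p <- runif(5); p <- p / sum(p)
    names(p) <- c("N", "L_MI", "R_MI", "R_MO", "R_S")
    out <- predict_with_threshold(p)
    top <- names(p)[which.max(p)]
    if (top != "N" || p[["N"]] >= 0.4) {
      expect_identical(out, top)
    } else {
      expect_identical(out, names(sort(p, decreasing = TRUE))[2])
    }
  }
})

test_that("baseline report covers the published sweep shapes", {
  feats <- small_features()
  rep <- evaluate_baselines(feats, folds = 3,
                            depth_grid = 1:10,
                            ntree_grid = c(5, 10, 20, 30, 50, 100),
                            seed = 3)
  expect_equal(nrow(rep$knn), 5 * 9)     # 9 accuracy points per movement
  expect_equal(nrow(rep$rf), 5 * 60)     # 10 x 6 grid per movement
  expect_true(all(rep$knn$accuracy >= 0 & rep$knn$accuracy <= 1))
  expect_true(all(rep$rf$accuracy >= 0 & rep$rf$accuracy <= 1))
})

test_that("1-NN scored on its own training set is perfect", {
  feats <- small_features()
  x <- movement_feature_subset(feats, "smiling")
  clf <- train_movement_classifier("smiling", x, feats$label, kind = "knn",
                                   k = 1, seed = 1)
  expect_equal(mean(predict(clf, x) == feats$label), 1.0)
})
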