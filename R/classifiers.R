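# First-level learners: per-movement RBF-kernel SVMs with grid-searched
# hyperparameters, K-NN and random-forest baselines, and the
# probability-threshold post-processing rule (the post-processing half of
# the imbalance strategy).

#' Default hyperparameter grids
#'
#' The full search ranges: cost C over 10^-3..10^8 (12 values) and kernel
#' width gamma over 10^-3..10^3 (7 values).
#'
#' @return Named list with `C` and `gamma` numeric vectors.
#' @export
default_svm_grid <- function() {
  list(C = 10^(-3:8), gamma = 10^(-3:3))
}

# stratified fold assignment: within each class, shuffle then deal round-robin
make_stratified_folds <- function(y, folds, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  seeds <- derive_seeds(seed, 1L)
  with_seed(seeds[1L], {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

# tree depth d -> terminal-node budget, capped at the training size
.cap_maxnodes <- function(depth, n) {
  as.integer(min(2^depth, max(n, 2L)))
}

# standardize with training statistics; zero-variance columns are centered
# only (RBF kernels need commensurate scales, constants carry no signal)
.fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}
.apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Exhaustively evaluates every (C, gamma) cell by stratified k-fold
#' cross-validation mean accuracy. Features are standardized with
#' training-fold statistics inside each fold. Ties are broken toward the
#' smallest C, then the smallest gamma; the result is invariant to the
#' order in which cells are evaluated.
#'
#' @param features Numeric matrix or data frame of predictors.
#' @param labels Class labels (one per row).
#' @param C_grid,gamma_grid Candidate values; defaults are the full ranges
#'   of [default_svm_grid()].
#' @param folds Number of CV folds (default 5).
#' @param seed Integer RNG seed (controls fold assignment).
#' @return List of class `"fp_grid_search"`: `best_C`, `best_gamma`,
#'   `cv_accuracy`, and the full `grid` table of mean CV accuracies.
#' @export
grid_search_svm <- function(features, labels,
                            C_grid = default_svm_grid()$C,
                            gamma_grid = default_svm_grid()$gamma,
                            folds = 5L, seed = 1L) {
  x <- as.matrix(features)
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("grid search needs at least two classes")
  if (any(table(y) < folds)) {
    stop("every class needs at least ", folds,
         " samples to build stratified ", folds, "-fold CV")
  }
  fold <- make_stratified_folds(y, folds, seed)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- NA_real_
  # precompute per-fold scaled splits once; reused by every grid cell
  splits <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    scaler <- .fit_scaler(x[tr, , drop = FALSE])
    list(xtr = .apply_scaler(x[tr, , drop = FALSE], scaler),
         ytr = y[tr],
         xva = .apply_scaler(x[!tr, , drop = FALSE], scaler),
         yva = y[!tr])
  })
  for (i in seq_len(nrow(grid))) {
    acc <- vapply(splits, function(s) {
      fit <- e1071::svm(s$xtr, s$ytr, kernel = "radial",
                        cost = grid$C[i], gamma = grid$gamma[i],
                        scale = FALSE)
      mean(predict(fit, s$xva) == s$yva)
    }, numeric(1))
    grid$accuracy[i] <- mean(acc)
  }
  # first maximum over the C-then-gamma sorted grid breaks ties as documented
  ord <- order(grid$C, grid$gamma)
  grid_sorted <- grid[ord, , drop = FALSE]
  best <- which(grid_sorted$accuracy == max(grid$accuracy))[1]
  structure(list(best_C = grid_sorted$C[best],
                 best_gamma = grid_sorted$gamma[best],
                 cv_accuracy = grid_sorted$accuracy[best],
                 grid = grid,
                 folds = folds, seed = seed),
            class = "fp_grid_search")
}

#' @export
print.fp_grid_search <- function(x, ...) {
  cat("RBF-SVM grid search:", nrow(x$grid), "cells,",
      x$folds, "-fold stratified CV\n")
  cat(sprintf("  best C = %g, gamma = %g, mean CV accuracy = %.3f\n",
              x$best_C, x$best_gamma, x$cv_accuracy))
  invisible(x)
}

#' Train one movement-specific classifier
#'
#' Fits a multiclass classifier on one movement's feature subset. The
#' default and primary model is an RBF-kernel SVM with pairwise-coupled
#' probability estimates; K-NN and random-forest baselines are available
#' through `kind`. SVM and K-NN features are standardized with training
#' statistics; the random forest is fit unscaled.
#'
#' @param movement One of the five voluntary movements.
#' @param features Predictor matrix/data frame whose columns must match the
#'   movement's feature schema (8 columns, 9 for whistling).
#' @param labels Class labels.
#' @param kind Model family: `"svm_rbf"` (default), `"knn"`,
#'   `"random_forest"`.
#' @param C,gamma SVM hyperparameters.
#' @param k K-NN neighbor count.
#' @param max_depth,n_estimators Random-forest hyperparameters.
#' @param seed Integer RNG seed; refitting with identical data, parameters
#'   and seed reproduces identical predictions.
#' @return Object of class `"fp_movement_classifier"`.
#' @export
train_movement_classifier <- function(movement, features, labels,
                                      kind = c("svm_rbf", "knn",
                                               "random_forest"),
                                      C = 10, gamma = 0.1, k = 5L,
                                      max_depth = 8L, n_estimators = 100L,
                                      seed = 1L) {
  kind <- match.arg(kind)
  movement <- match.arg(movement, fp_classifier_movements())
  expected <- movement_feature_names(movement)
  x <- as.matrix(features)
  if (ncol(x) != length(expected)) {
    stop("movement '", movement, "' expects ", length(expected),
         " feature columns, got ", ncol(x))
  }
  if (!is.null(colnames(x)) && !identical(colnames(x), expected)) {
    if (setequal(colnames(x), expected)) {
      x <- x[, expected, drop = FALSE]
    } else {
      stop("feature columns do not match the '", movement, "' schema")
    }
  }
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("training data contain a single class")

  scaler <- if (kind == "random_forest") NULL else .fit_scaler(x)
  xs <- if (is.null(scaler)) x else .apply_scaler(x, scaler)
  model <- switch(kind,
    svm_rbf = with_seed(seed,
      e1071::svm(xs, y, kernel = "radial", cost = C, gamma = gamma,
                 probability = TRUE, scale = FALSE)),
    knn = list(x = xs, y = y, k = as.integer(k)),
    random_forest = with_seed(seed,
      randomForest::randomForest(x, y, ntree = as.integer(n_estimators),
                                 maxnodes = .cap_maxnodes(max_depth,
                                                          nrow(x))))
  )
  structure(list(movement = movement, kind = kind,
                 hyperparameters = switch(kind,
                   svm_rbf = list(C = C, gamma = gamma),
                   knn = list(k = k),
                   random_forest = list(max_depth = max_depth,
                                        n_estimators = n_estimators)),
                 model = model, scaler = scaler,
                 classes = levels(y), feature_names = expected,
                 seed = seed),
            class = "fp_movement_classifier")
}

#' @export
print.fp_movement_classifier <- function(x, ...) {
  cat("Movement classifier [", x$movement, "]: ", x$kind, ", ",
      length(x$feature_names), " features, classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict with a movement classifier
#'
#' @param object An `fp_movement_classifier`.
#' @param newdata Feature matrix/data frame matching the movement schema.
#' @param type `"class"` for labels, `"prob"` for the class-probability
#'   matrix (rows sum to 1).
#' @param ... Unused.
#' @return Character vector of labels or a probability matrix.
#' @export
predict.fp_movement_classifier <- function(object, newdata,
                                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && setequal(colnames(x), object$feature_names)) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  if (ncol(x) != length(object$feature_names)) {
    stop("newdata must have ", length(object$feature_names),
         " feature columns for movement '", object$movement, "'")
  }
  xs <- if (is.null(object$scaler)) x else .apply_scaler(x, object$scaler)
  prob <- switch(object$kind,
    svm_rbf = {
      pr <- predict(object$model, xs, probability = TRUE)
      p <- attr(pr, "probabilities")
      p[, object$classes, drop = FALSE]
    },
    knn = {
      # neighbor-vote proportions as the probability estimate
      votes <- matrix(0, nrow = nrow(xs), ncol = length(object$classes),
                      dimnames = list(NULL, object$classes))
      pr <- class::knn(object$model$x, xs, object$model$y,
                       k = object$model$k, prob = TRUE, use.all = TRUE)
      # knn only reports the winning proportion; rebuild full vote shares
      # from neighbor distances is not exposed, so distribute the
      # remainder uniformly over the other classes
      win <- as.character(pr)
      pwin <- attr(pr, "prob")
      for (i in seq_len(nrow(xs))) {
        votes[i, ] <- (1 - pwin[i]) / (length(object$classes) - 1)
        votes[i, win[i]] <- pwin[i]
      }
      votes
    },
    random_forest = {
      p <- predict(object$model, x, type = "prob")
      p[, object$classes, drop = FALSE]
    }
  )
  rownames(prob) <- NULL
  if (type == "prob") return(prob)
  object$classes[max.col(prob, ties.method = "first")]
}

#' Threshold-moving decision rule
#'
#' The post-processing half of the imbalance strategy: by default the
#' predicted class is the probability argmax, but when the normal class
#' wins with a probability below the threshold it is excluded and the
#' second-ranked class is returned instead. FP-class argmaxes are never
#' altered.
#'
#' @param prob Named probability vector, or a matrix with one row per
#'   sample and class columns.
#' @param threshold Minimum probability for the normal class to keep an
#'   argmax win (default 0.4).
#' @param normal Symbol of the normal class (default `"N"`).
#' @return Predicted label(s).
#' @export
#' @examples
#' predict_with_threshold(c(N = 0.38, R_MO = 0.30, L_MI = 0.20,
#'                          R_MI = 0.07, R_S = 0.05))  # "R_MO"
predict_with_threshold <- function(prob, threshold = 0.4, normal = "N") {
  if (is.matrix(prob)) {
    return(apply(prob, 1, predict_with_threshold,
                 threshold = threshold, normal = normal))
  }
  if (length(prob) == 0) stop("empty probability vector")
  if (is.null(names(prob))) stop("probability vector must be named")
  ord <- order(prob, decreasing = TRUE)
  top <- names(prob)[ord[1]]
  if (top == normal && prob[ord[1]] < threshold && length(prob) > 1) {
    return(names(prob)[ord[2]])
  }
  top
}

#' Baseline model sweeps
#'
#' Per-movement cross-validated accuracy for the two baseline families:
#' a K-NN curve over the neighbor counts and a random-forest grid over
#' (max_depth, n_estimators). Used to justify the choice of SVMs as the
#' first-level learners.
#'
#' @param features Feature table from [extract_features()] (41 columns
#'   plus `label`).
#' @param labels Optional label vector; defaults to `features$label`.
#' @param k_range K-NN neighbor counts (default 1..9).
#' @param depth_grid,ntree_grid Random-forest grids (defaults 1..10 and
#'   5, 10, 20, 30, 50, 100).
#' @param folds CV folds.
#' @param seed Integer RNG seed.
#' @return List of class `"fp_baseline_report"` with data frames `knn`
#'   (movement, k, accuracy) and `rf` (movement, max_depth, n_estimators,
#'   accuracy).
#' @export
evaluate_baselines <- function(features, labels = NULL,
                               k_range = 1:9,
                               depth_grid = 1:10,
                               ntree_grid = c(5, 10, 20, 30, 50, 100),
                               folds = 5L, seed = 1L) {
  if (is.null(labels)) labels <- features$label
  y <- factor(as.character(labels))
  fold <- make_stratified_folds(y, folds, seed)
  seeds <- derive_seeds(seed, 2L)

  knn_rows <- list()
  rf_rows <- list()
  for (m in fp_classifier_movements()) {
    x <- as.matrix(movement_feature_subset(features, m))
    splits <- lapply(seq_len(folds), function(f) {
      tr <- fold != f
      scaler <- .fit_scaler(x[tr, , drop = FALSE])
      list(xtr_s = .apply_scaler(x[tr, , drop = FALSE], scaler),
           xva_s = .apply_scaler(x[!tr, , drop = FALSE], scaler),
           xtr = x[tr, , drop = FALSE], xva = x[!tr, , drop = FALSE],
           ytr = y[tr], yva = y[!tr])
    })
    for (k in k_range) {
      acc <- vapply(splits, function(s) {
        pr <- with_seed(seeds[1],
          class::knn(s$xtr_s, s$xva_s, s$ytr, k = k))
        mean(pr == s$yva)
      }, numeric(1))
      knn_rows[[length(knn_rows) + 1L]] <-
        data.frame(movement = m, k = k, accuracy = mean(acc))
    }
    for (d in depth_grid) for (nt in ntree_grid) {
      acc <- vapply(splits, function(s) {
        fit <- with_seed(seeds[2],
          randomForest::randomForest(s$xtr, s$ytr,
                                     ntree = as.integer(nt),
                                     maxnodes = .cap_maxnodes(d,
                                                              nrow(s$xtr))))
        mean(predict(fit, s$xva) == s$yva)
      }, numeric(1))
      rf_rows[[length(rf_rows) + 1L]] <-
        data.frame(movement = m, max_depth = d, n_estimators = nt,
                   accuracy = mean(acc))
    }
  }
  structure(list(knn = do.call(rbind, knn_rows),
                 rf = do.call(rbind, rf_rows)),
            class = "fp_baseline_report")
}
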