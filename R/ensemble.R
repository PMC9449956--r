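# Second-level learner (rule-based vote combiner), the fp_ensemble model
# object, and end-to-end pipeline orchestration.

#' Combine the five first-level votes
#'
#' Rule-based second-level decision over the five movement classifiers:
#' \enumerate{
#'   \item strict majority (>= 3 votes) wins (`majority`);
#'   \item a unique class with 2 votes wins (`plurality`);
#'   \item two classes tied at 2 votes: if exactly one of them is the
#'     normal class, the other wins (`tie_rule_a`); otherwise the tied
#'     class with the larger probability mass summed over the five
#'     classifiers wins (`tie_rule_b`);
#'   \item all five votes distinct: the class with the highest summed
#'     probability wins (`prob_sum_fallback`).
#' }
#' The decision is deterministic and invariant to the order in which the
#' classifiers are listed; residual probability ties are broken by the
#' canonical class order.
#'
#' @param votes Character vector of exactly 5 predicted labels.
#' @param probs List of 5 named probability vectors (one per classifier).
#'   May be `NULL` when no 2-2 tie or all-distinct case needs resolving.
#' @param normal Symbol of the normal class.
#' @return Object of class `"fp_ensemble_prediction"`: `votes`,
#'   `vote_counts`, `prob_sum`, `final`, `rationale`.
#' @export
#' @examples
#' combine_votes(c("R_MO", "R_MO", "R_MO", "N", "L_MI"))$final  # "R_MO"
combine_votes <- function(votes, probs = NULL, normal = "N") {
  if (length(votes) != 5L) stop("exactly 5 first-level votes are required")
  if (!is.null(probs) && length(probs) != 5L) {
    stop("probs must contain one probability vector per classifier")
  }
  counts <- table(votes)
  prob_sum <- NULL
  if (!is.null(probs)) {
    cls <- sort(unique(unlist(lapply(probs, names))))
    prob_sum <- stats::setNames(numeric(length(cls)), cls)
    for (p in probs) prob_sum[names(p)] <- prob_sum[names(p)] + p
  }
  need_probs <- function() {
    if (is.null(prob_sum)) {
      stop("probability vectors are required to resolve this vote pattern")
    }
    prob_sum
  }
  # stable order among equals: canonical class order, then alphabetical
  canon <- function(x) {
    x[order(match(x, fp_classes(), nomatch = length(fp_classes()) + 1L), x)]
  }
  top <- max(counts)
  leaders <- canon(names(counts)[counts == top])
  if (top >= 3L) {
    final <- leaders[1]; rationale <- "majority"
  } else if (top == 2L && length(leaders) == 1L) {
    final <- leaders[1]; rationale <- "plurality"
  } else if (top == 2L) {
    if (sum(leaders == normal) == 1L && length(leaders) == 2L) {
      final <- setdiff(leaders, normal); rationale <- "tie_rule_a"
    } else {
      ps <- need_probs()
      mass <- ps[leaders]
      mass[is.na(mass)] <- 0
      final <- leaders[which.max(mass)]; rationale <- "tie_rule_b"
    }
  } else {
    ps <- need_probs()
    ord <- canon(names(ps))
    final <- ord[which.max(ps[ord])]; rationale <- "prob_sum_fallback"
  }
  structure(list(votes = votes, vote_counts = counts, prob_sum = prob_sum,
                 final = final, rationale = rationale),
            class = "fp_ensemble_prediction")
}

#' @export
print.fp_ensemble_prediction <- function(x, ...) {
  cat("Ensemble vote: [", paste(x$votes, collapse = ", "), "] -> ",
      x$final, " (", x$rationale, ")\n", sep = "")
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits a labeled table so that per-class proportions in both parts stay
#' within one sample of the global proportions. The test allocation rounds
#' down per class; the remainder (to reach the overall test fraction) is
#' assigned by largest fractional remainder.
#'
#' @param data Labeled data frame.
#' @param ratio Training fraction (default 0.8, i.e. a 4:1 split).
#' @param seed Integer RNG seed.
#' @param label Name of the label column.
#' @return List with `train` and `test` data frames (disjoint, union =
#'   input).
#' @export
stratified_split <- function(data, ratio = 0.8, seed = 1L, label = "label") {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  y <- as.character(data[[label]])
  counts <- table(y)
  if (any(counts < 2)) {
    stop("class '", names(counts)[counts < 2][1],
         "' has fewer than 2 samples; cannot stratify")
  }
  test_frac <- 1 - ratio
  exact <- counts * test_frac
  n_test_class <- floor(exact)
  total_test <- round(sum(counts) * test_frac)
  short <- total_test - sum(n_test_class)
  if (short > 0) {
    rem <- exact - n_test_class
    extra <- order(-rem, names(counts))[seq_len(min(short, length(counts)))]
    n_test_class[extra] <- n_test_class[extra] + 1
  }
  test_idx <- integer(0)
  seeds <- derive_seeds(seed, 1L)
  with_seed(seeds[1L], {
    for (cls in names(counts)) {
      idx <- which(y == cls)
      test_idx <- c(test_idx, idx[sample.int(length(idx),
                                             n_test_class[[cls]])])
    }
  })
  train <- data[setdiff(seq_len(nrow(data)), test_idx), , drop = FALSE]
  test <- data[sort(test_idx), , drop = FALSE]
  rownames(train) <- NULL
  rownames(test) <- NULL
  list(train = train, test = test)
}

#' Fit the two-level facial-palsy ensemble
#'
#' The central model fit: for each of the five voluntary movements a
#' movement-specific RBF-kernel SVM is (optionally grid-search tuned and)
#' trained on that movement's feature subset; predictions are fused by the
#' rule-based combiner of [combine_votes()] after the threshold-moving
#' rule of [predict_with_threshold()] is applied to each first-level
#' probability vector.
#'
#' @param data Feature table from [extract_features()]: the 41 feature
#'   columns plus a label column.
#' @param label Name of the label column.
#' @param C_grid,gamma_grid Hyperparameter candidates per movement; a
#'   single value each skips the search.
#' @param folds Stratified CV folds for tuning.
#' @param threshold Normal-class probability threshold (default 0.4).
#' @param seed Integer RNG seed.
#' @return Object of class `"fp_ensemble"` with one fitted classifier and
#'   grid-search result per movement.
#' @seealso [predict.fp_ensemble()], [run_pipeline()]
#' @export
fp_ensemble <- function(data, label = "label",
                        C_grid = 10^seq(-1, 5, by = 2),
                        gamma_grid = 10^(-2:1),
                        folds = 5L, threshold = 0.4, seed = 1L) {
  y <- as.character(data[[label]])
  movements <- fp_classifier_movements()
  seeds <- derive_seeds(seed, length(movements))
  classifiers <- list()
  searches <- list()
  for (i in seq_along(movements)) {
    m <- movements[i]
    x <- movement_feature_subset(data, m)
    if (length(C_grid) > 1L || length(gamma_grid) > 1L) {
      gs <- grid_search_svm(x, y, C_grid = C_grid, gamma_grid = gamma_grid,
                            folds = folds, seed = seeds[i])
      searches[[m]] <- gs
      C <- gs$best_C; gamma <- gs$best_gamma
    } else {
      C <- C_grid[1]; gamma <- gamma_grid[1]
    }
    classifiers[[m]] <- train_movement_classifier(
      m, x, y, kind = "svm_rbf", C = C, gamma = gamma, seed = seeds[i])
  }
  structure(list(classifiers = classifiers, grid_searches = searches,
                 threshold = threshold, classes = sort(unique(y)),
                 n_train = nrow(data), seed = seed,
                 call = match.call()),
            class = "fp_ensemble")
}

#' Predict facial-palsy severity with the ensemble
#'
#' Runs the five movement classifiers, applies the threshold-moving rule
#' to each first-level probability vector (or, optionally, only at the
#' ensemble level to the summed probabilities), and fuses the votes with
#' the rule-based combiner.
#'
#' @param object A fitted [fp_ensemble()].
#' @param newdata Feature table with the 41 schema columns.
#' @param type `"class"` for the final labels, `"full"` for a list of
#'   per-record `fp_ensemble_prediction` objects.
#' @param threshold Override of the fitted threshold.
#' @param threshold_level Where the threshold rule is applied:
#'   `"classifier"` (default; each first-level vote) or `"ensemble"`
#'   (only the fused decision).
#' @param ... Unused.
#' @return Character vector of labels, or a list of detailed predictions.
#' @export
predict.fp_ensemble <- function(object, newdata, type = c("class", "full"),
                                threshold = object$threshold,
                                threshold_level = c("classifier",
                                                    "ensemble"), ...) {
  type <- match.arg(type)
  threshold_level <- match.arg(threshold_level)
  movements <- names(object$classifiers)
  n <- nrow(newdata)
  probs <- lapply(object$classifiers, function(clf) {
    predict(clf, movement_feature_subset(newdata, clf$movement),
            type = "prob")
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- lapply(probs, function(p) p[i, ])
    votes <- vapply(p_i, function(p) {
      if (threshold_level == "classifier") {
        predict_with_threshold(p, threshold = threshold)
      } else {
        names(p)[which.max(p)]
      }
    }, character(1))
    pred <- combine_votes(unname(votes), unname(p_i))
    if (threshold_level == "ensemble" && pred$final == "N") {
      ps <- pred$prob_sum / length(p_i)
      if (ps[["N"]] < threshold && length(ps) > 1L) {
        pred$final <- predict_with_threshold(ps, threshold = threshold)
        pred$rationale <- paste0(pred$rationale, "+threshold")
      }
    }
    out[[i]] <- pred
  }
  if (type == "full") return(out)
  vapply(out, function(p) p$final, character(1))
}

#' @export
print.fp_ensemble <- function(x, ...) {
  cat("Two-level facial-palsy ensemble\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  first level: 5 movement RBF-SVMs,", x$n_train,
      "training records\n")
  cat("  threshold-moving: normal demoted below P =", x$threshold, "\n")
  invisible(x)
}

#' @export
summary.fp_ensemble <- function(object, ...) {
  hp <- do.call(rbind, lapply(object$classifiers, function(clf) {
    gs <- object$grid_searches[[clf$movement]]
    data.frame(movement = clf$movement,
               C = clf$hyperparameters$C,
               gamma = clf$hyperparameters$gamma,
               cv_accuracy = if (is.null(gs)) NA_real_ else gs$cv_accuracy)
  }))
  rownames(hp) <- NULL
  structure(list(hyperparameters = hp, threshold = object$threshold,
                 classes = object$classes, n_train = object$n_train),
            class = "summary.fp_ensemble")
}

#' @export
print.summary.fp_ensemble <- function(x, ...) {
  cat("Two-level facial-palsy ensemble (", x$n_train, " training records, ",
      length(x$classes), " classes)\n", sep = "")
  cat("Per-movement RBF-SVM hyperparameters:\n")
  print(x$hyperparameters, row.names = FALSE)
  cat("Threshold-moving: normal class demoted below P =", x$threshold, "\n")
  invisible(x)
}

#' Plot grid-search accuracy surfaces
#'
#' Displays the tuning landscape of one movement classifier as an image of
#' mean CV accuracy over the log10(C) x log10(gamma) grid.
#'
#' @param x A fitted [fp_ensemble()] (with grid searches).
#' @param movement Movement to display (default: first).
#' @param ... Passed to [graphics::image()].
#' @export
plot.fp_ensemble <- function(x, movement = names(x$classifiers)[1], ...) {
  gs <- x$grid_searches[[movement]]
  if (is.null(gs)) stop("no grid search stored for movement '",
                        movement, "'")
  Cs <- sort(unique(gs$grid$C)); gs_g <- sort(unique(gs$grid$gamma))
  z <- matrix(NA_real_, length(Cs), length(gs_g))
  z[cbind(match(gs$grid$C, Cs), match(gs$grid$gamma, gs_g))] <-
    gs$grid$accuracy
  graphics::image(log10(Cs), log10(gs_g), z,
                  xlab = "log10(C)", ylab = "log10(gamma)",
                  main = paste0("CV accuracy: ", movement), ...)
  invisible(x)
}

#' Pipeline configuration
#'
#' @param ratio Training fraction of the stratified split (default 0.8).
#' @param folds CV folds for tuning (default 5).
#' @param seed Master RNG seed.
#' @param threshold Normal-class probability threshold (default 0.4).
#' @param undersample Apply random undersampling to the majority class.
#' @param undersample_class Class to undersample (default `"N"`).
#' @param undersample_to Target count (default 289).
#' @param augment Apply SMOTE to the training part.
#' @param augment_before_split Apply SMOTE to the whole dataset before
#'   splitting (the leakage-prone ordering; off by default).
#' @param smote_k SMOTE neighbor count.
#' @param C_grid,gamma_grid SVM tuning grids (defaults: a 4 x 4 subgrid of
#'   the full ranges).
#' @param threshold_level Where threshold moving is applied (see
#'   [predict.fp_ensemble()]).
#' @return List of class `"fp_pipeline_config"`.
#' @export
pipeline_config <- function(ratio = 0.8, folds = 5L, seed = 1L,
                            threshold = 0.4,
                            undersample = TRUE, undersample_class = "N",
                            undersample_to = 289L,
                            augment = TRUE, augment_before_split = FALSE,
                            smote_k = 5L,
                            C_grid = 10^seq(-1, 5, by = 2),
                            gamma_grid = 10^(-2:1),
                            threshold_level = "classifier") {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  if (folds < 2) stop("folds must be >= 2")
  structure(as.list(environment()), class = "fp_pipeline_config")
}

#' Run the end-to-end classification pipeline
#'
#' Feature transformation, undersampling, stratified splitting, SMOTE
#' augmentation of the training part, per-movement tuning and training,
#' thresholded first-level prediction, rule-based vote fusion, and
#' evaluation on the held-out test set.
#'
#' @param records An `fp_cohort` of raw FAU records.
#' @param config An [pipeline_config()].
#' @return Object of class `"fp_report"`: the fitted `model`, held-out
#'   `confusion` matrix, per-class `metrics`, per-classifier test metrics
#'   (with and without threshold moving), the data sizes at each stage and
#'   the seeds used.
#' @export
run_pipeline <- function(records, config = pipeline_config()) {
  stopifnot(inherits(config, "fp_pipeline_config"))
  seeds <- derive_seeds(config$seed, 4L)
  stage <- "feature transformation"
  report <- tryCatch({
    features <- extract_features(records)
    sizes <- list(records = nrow(features))

    stage <- "undersampling"
    if (config$undersample) {
      n_cls <- sum(features$label == config$undersample_class)
      target <- min(n_cls, config$undersample_to)
      features <- random_undersample(features, config$undersample_class,
                                     target, seed = seeds[1])
    }
    sizes$after_undersampling <- nrow(features)

    stage <- "augmentation (pre-split)"
    if (config$augment && config$augment_before_split) {
      features <- smote_oversample(features, k = config$smote_k,
                                   seed = seeds[2])
    }

    stage <- "stratified split"
    parts <- stratified_split(features, ratio = config$ratio,
                              seed = seeds[3])
    train <- parts$train; test <- parts$test
    sizes$train <- nrow(train); sizes$test <- nrow(test)

    stage <- "augmentation"
    if (config$augment && !config$augment_before_split) {
      train <- smote_oversample(train, k = config$smote_k, seed = seeds[2])
    }
    sizes$train_augmented <- nrow(train)

    stage <- "ensemble training"
    model <- fp_ensemble(train, C_grid = config$C_grid,
                         gamma_grid = config$gamma_grid,
                         folds = config$folds,
                         threshold = config$threshold, seed = seeds[4])

    stage <- "prediction"
    pred <- predict(model, test, threshold_level = config$threshold_level)
    classes <- model$classes
    cm <- confusion_matrix(test$label, pred, classes)

    stage <- "evaluation"
    per_clf <- .per_classifier_metrics(model, test, config$threshold)

    structure(list(model = model,
                   confusion = cm,
                   metrics = per_class_metrics(cm),
                   classifier_metrics = per_clf,
                   hyperparameters = summary(model)$hyperparameters,
                   sizes = sizes,
                   seeds = seeds, config = config),
              class = "fp_report")
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  report
}

# test-set metrics of each first-level classifier, with and without the
# threshold-moving rule
.per_classifier_metrics <- function(model, test, threshold) {
  rows <- list()
  for (clf in model$classifiers) {
    p <- predict(clf, movement_feature_subset(test, clf$movement),
                 type = "prob")
    raw <- clf$classes[max.col(p, ties.method = "first")]
    thr <- predict_with_threshold(p, threshold = threshold)
    for (mode in c(FALSE, TRUE)) {
      pred <- if (mode) thr else raw
      cm <- confusion_matrix(test$label, pred, model$classes)
      agg <- aggregate_metrics(per_class_metrics(cm))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(movement = clf$movement, threshold_moving = mode),
        agg)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.fp_report <- function(x, ...) {
  cat("Facial-palsy classification pipeline report\n")
  cat("  records:", x$sizes$records,
      "| after undersampling:", x$sizes$after_undersampling,
      "| train:", x$sizes$train,
      "(augmented:", paste0(x$sizes$train_augmented, ")"),
      "| test:", x$sizes$test, "\n")
  agg <- aggregate_metrics(x$metrics)
  cat(sprintf("  ensemble test: micro accuracy %.1f%%, macro F1 %.1f%%\n",
              agg$micro_accuracy, agg$macro_f1))
  cat("Confusion matrix (rows = true):\n")
  print(unclass(x$confusion))
  invisible(x)
}
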