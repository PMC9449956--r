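# Evaluation: confusion matrices, per-class one-vs-rest metrics and
# repeated cross-validation robustness reports.

#' Confusion matrix
#'
#' Counts of (true, predicted) label pairs in a fixed class order; rows
#' are the true classes, columns the predictions.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param class_order Ordered class list; any label outside it is an
#'   error.
#' @return Integer matrix of class `"fp_confusion"`.
#' @export
confusion_matrix <- function(y_true, y_pred,
                             class_order = sort(unique(c(y_true, y_pred)))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad)) {
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "))
  }
  cm <- table(true = factor(y_true, levels = class_order),
              predicted = factor(y_pred, levels = class_order))
  cm <- unclass(cm)
  storage.mode(cm) <- "integer"
  structure(cm, class = c("fp_confusion", "matrix"))
}

#' Read a confusion matrix from CSV
#'
#' Expects a header row of predicted-class names and a first column of
#' true-class names (e.g. an externally reported matrix to be re-scored
#' with [per_class_metrics()]).
#'
#' @param path CSV file path.
#' @return An `fp_confusion` matrix.
#' @export
read_confusion_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  cm <- as.matrix(df)
  if (nrow(cm) != ncol(cm) || !setequal(rownames(cm), colnames(cm))) {
    stop("confusion matrix must be square with matching class names")
  }
  cm <- cm[, rownames(cm), drop = FALSE]
  storage.mode(cm) <- "integer"
  names(dimnames(cm)) <- c("true", "predicted")
  structure(cm, class = c("fp_confusion", "matrix"))
}

#' @export
print.fp_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true class):\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class one-vs-rest metrics
#'
#' For each class c: TP = cm[c, c], FN = row sum - TP, FP = column sum -
#' TP, TN = the rest. Reported in percent: one-vs-rest accuracy
#' 100 (TP + TN) / n, precision 100 TP / (TP + FP), sensitivity
#' 100 TP / (TP + FN), specificity 100 TN / (TN + FP) and F1 (harmonic
#' mean of precision and sensitivity). Zero-denominator metrics are
#' reported as `NA` and flagged `undefined`, never coerced to 0 or 100.
#'
#' @param cm An [confusion_matrix()].
#' @return Data frame, one row per class: counts, the five percent
#'   metrics, and an `undefined` flag.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  if (length(cm) == 0 || sum(cm) == 0) stop("empty confusion matrix")
  n <- sum(cm)
  classes <- rownames(cm)
  out <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    precision <- pct(tp, tp + fp)
    sensitivity <- pct(tp, tp + fn)
    f1 <- if (is.na(precision) || is.na(sensitivity) ||
              precision + sensitivity == 0) NA_real_
          else 2 * precision * sensitivity / (precision + sensitivity)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               accuracy = pct(tp + tn, n),
               precision = precision,
               sensitivity = sensitivity,
               specificity = pct(tn, tn + fp),
               f1 = f1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$undefined <- is.na(res$precision) | is.na(res$sensitivity) |
    is.na(res$specificity) | is.na(res$f1)
  rownames(res) <- NULL
  class(res) <- c("fp_class_metrics", "data.frame")
  res
}

#' @export
print.fp_class_metrics <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("accuracy", "precision", "sensitivity", "specificity",
                "f1")) {
    y[[col]] <- round_away(y[[col]], 1)
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Aggregate per-class metrics
#'
#' Macro averages (unweighted mean over classes, `NA` metrics dropped)
#' plus the micro accuracy trace(cm) / n recomputed from the counts.
#'
#' @param metrics A [per_class_metrics()] table.
#' @return One-row data frame: `micro_accuracy`, `macro_accuracy`,
#'   `macro_precision`, `macro_sensitivity`, `macro_specificity`,
#'   `macro_f1` (all percent).
#' @export
aggregate_metrics <- function(metrics) {
  n <- metrics$tp[1] + metrics$fp[1] + metrics$fn[1] + metrics$tn[1]
  data.frame(
    micro_accuracy = 100 * sum(metrics$tp) / n,
    macro_accuracy = mean(metrics$accuracy, na.rm = TRUE),
    macro_precision = mean(metrics$precision, na.rm = TRUE),
    macro_sensitivity = mean(metrics$sensitivity, na.rm = TRUE),
    macro_specificity = mean(metrics$specificity, na.rm = TRUE),
    macro_f1 = mean(metrics$f1, na.rm = TRUE)
  )
}

#' Repeated-CV robustness report
#'
#' Evaluates each movement classifier by stratified k-fold cross-validation
#' repeated with different splits, with and without SMOTE augmentation of
#' the training folds, and reports mean and standard deviation of pooled
#' accuracy and macro precision, sensitivity and F1 per repetition.
#' Augmentation is always applied inside the training folds only, so
#' validation folds contain no synthetic samples.
#'
#' @param data Labeled feature table (41 features + `label`).
#' @param C,gamma SVM hyperparameters used for every movement model.
#' @param folds CV folds per repetition (default 5).
#' @param repetitions Number of repeated splits (default 5).
#' @param augment Conditions to run (default both `TRUE` and `FALSE`).
#' @param augment_before_folding If `TRUE`, SMOTE is applied to the whole
#'   dataset before fold assignment, so validation folds also contain
#'   synthetic samples. This mirrors the protocol under which balanced
#'   augmented evaluation raises the mean and shrinks the spread of the
#'   scores; the default (`FALSE`) keeps validation folds free of
#'   synthetic samples.
#' @param smote_k SMOTE neighbor count.
#' @param seed Master seed; each repetition uses a derived split seed.
#' @param label Name of the label column.
#' @return Data frame of class `"fp_robustness"`: one row per (condition,
#'   movement, metric) with `mean` and `sd` columns (percent).
#' @export
cv_robustness <- function(data, C = 10, gamma = 0.1, folds = 5L,
                          repetitions = 5L, augment = c(TRUE, FALSE),
                          augment_before_folding = FALSE,
                          smote_k = 5L, seed = 1L, label = "label") {
  if (repetitions < 2) stop("repetitions must be >= 2")
  y <- factor(as.character(data[[label]]))
  rep_seeds <- derive_seeds(seed, repetitions)
  rows <- list()
  for (aug in augment) {
    # per repetition x movement metric values
    vals <- array(NA_real_,
                  dim = c(repetitions, 5L, 4L),
                  dimnames = list(NULL, fp_classifier_movements(),
                                  c("accuracy", "precision", "sensitivity",
                                    "f1")))
    for (r in seq_len(repetitions)) {
      dat_r <- data
      if (aug && augment_before_folding) {
        dat_r <- smote_oversample(dat_r, k = smote_k,
                                  seed = rep_seeds[r], label = label)
      }
      y_r <- factor(as.character(dat_r[[label]]), levels = levels(y))
      fold <- make_stratified_folds(y_r, folds, rep_seeds[r])
      for (m in fp_classifier_movements()) {
        preds <- character(length(y_r))
        for (f in seq_len(folds)) {
          tr_idx <- which(fold != f)
          va_idx <- which(fold == f)
          tr <- dat_r[tr_idx, , drop = FALSE]
          if (aug && !augment_before_folding) {
            tr <- smote_oversample(tr, k = smote_k, seed = rep_seeds[r] %%
                                     1e6 + f, label = label)
          }
          clf <- train_movement_classifier(
            m, movement_feature_subset(tr, m), tr[[label]],
            kind = "svm_rbf", C = C, gamma = gamma, seed = rep_seeds[r])
          preds[va_idx] <- predict(
            clf, movement_feature_subset(dat_r[va_idx, , drop = FALSE], m))
        }
        cm <- confusion_matrix(as.character(y_r), preds, levels(y))
        agg <- aggregate_metrics(per_class_metrics(cm))
        vals[r, m, ] <- c(agg$micro_accuracy, agg$macro_precision,
                          agg$macro_sensitivity, agg$macro_f1)
      }
    }
    for (m in fp_classifier_movements()) {
      for (met in dimnames(vals)[[3]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          augmented = aug, movement = m, metric = met,
          mean = mean(vals[, m, met]), sd = stats::sd(vals[, m, met]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fp_robustness", "data.frame")
  out
}

#' @export
print.fp_robustness <- function(x, ...) {
  y <- as.data.frame(x)
  y$summary <- sprintf("%.0f ± %.0f", round_away(y$mean, 0),
                       round_away(y$sd, 0))
  print(y[, c("augmented", "movement", "metric", "summary")],
        row.names = FALSE)
  invisible(x)
}
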