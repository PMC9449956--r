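# Hybrid imbalance handling, preprocessing half: random undersampling of
# the majority class and SMOTE oversampling of the minority classes.
# (The post-processing half, threshold moving, lives with the classifiers.)

# numeric feature columns of a labeled feature table
.feature_cols <- function(data, label = "label") {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))],
          c(label, "record_id", "provenance"))
}

#' Randomly undersample one class
#'
#' Reduces `target_class` to exactly `target_n` rows drawn uniformly
#' without replacement; all other classes are untouched and row order is
#' otherwise preserved.
#'
#' @param data Labeled feature table (one row per record).
#' @param target_class Class symbol to downsample.
#' @param target_n Rows to keep; must not exceed the current class count.
#' @param seed Integer RNG seed.
#' @param label Name of the label column.
#' @return The reduced data frame.
#' @export
random_undersample <- function(data, target_class, target_n, seed = 1L,
                               label = "label") {
  cnt <- sum(data[[label]] == target_class)
  if (target_n > cnt) {
    stop("target_n (", target_n, ") exceeds the ", target_class,
         " class count (", cnt, ")")
  }
  if (target_n < 0) stop("target_n must be non-negative")
  idx <- which(data[[label]] == target_class)
  keep <- with_seed(seed, idx[sample.int(length(idx), target_n)])
  out <- data[sort(c(setdiff(seq_len(nrow(data)), idx), keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SMOTE oversampling to a uniform class histogram
#'
#' Brings every class up to the majority-class count by synthesizing
#' minority samples: a synthetic sample is `x_i + u * (x_nn - x_i)` with
#' `u ~ Uniform(0, 1)`, where `x_i` is a seed sample drawn uniformly (with
#' replacement) from the class and `x_nn` one of its `k` nearest same-class
#' neighbors in Euclidean feature space, chosen uniformly. Original rows
#' are preserved verbatim; synthetic rows are appended and flagged in a
#' `provenance` column.
#'
#' @param data Labeled feature table.
#' @param k Number of nearest neighbors (default 5). If `k` is not smaller
#'   than a class's size it is reduced to size - 1 with a warning.
#' @param seed Integer RNG seed.
#' @param label Name of the label column.
#' @return Data frame with a uniform class histogram and a `provenance`
#'   column in {"original", "synthetic"}.
#' @export
smote_oversample <- function(data, k = 5L, seed = 1L, label = "label") {
  if (k < 1) stop("k must be >= 1")
  counts <- table(data[[label]])
  target <- max(counts)
  deficient <- names(counts)[counts < target]
  small <- names(counts)[counts < 2]
  if (length(intersect(deficient, small))) {
    stop("class '", intersect(deficient, small)[1],
         "' has fewer than 2 samples; SMOTE needs at least 2")
  }
  fcols <- .feature_cols(data, label)
  if (!"provenance" %in% names(data)) data$provenance <- "original"

  synth <- list()
  seeds <- derive_seeds(seed, length(deficient))
  for (ci in seq_along(deficient)) {
    cls <- deficient[ci]
    rows <- data[data[[label]] == cls, , drop = FALSE]
    x <- as.matrix(rows[, fcols, drop = FALSE])
    n <- nrow(x)
    k_use <- k
    if (k_use >= n) {
      warning("class '", cls, "': k reduced from ", k, " to ", n - 1)
      k_use <- n - 1L
    }
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    # k nearest same-class neighbors per sample (ties by row order)
    nn <- matrix(apply(d, 1, function(dr) order(dr)[seq_len(k_use)]),
                 ncol = n)
    deficit <- target - n
    new_rows <- with_seed(seeds[ci], {
      i <- sample.int(n, deficit, replace = TRUE)
      j_pick <- sample.int(k_use, deficit, replace = TRUE)
      u <- stats::runif(deficit)
      xi <- x[i, , drop = FALSE]
      xnn <- x[nn[cbind(j_pick, i)], , drop = FALSE]
      xi + u * (xnn - xi)
    })
    blk <- rows[rep(1L, deficit), , drop = FALSE]
    blk[, fcols] <- new_rows
    blk$provenance <- "synthetic"
    if ("record_id" %in% names(blk)) {
      blk$record_id <- sprintf("%s_smote_%04d", cls, seq_len(deficit))
    }
    synth[[cls]] <- blk
  }
  out <- rbind(data, do.call(rbind, synth))
  rownames(out) <- NULL
  out
}
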