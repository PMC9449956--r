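# Feature transformation: raw per-movement FAU activations -> animation
# symmetry indices (ASIs) and rest-difference facial-function grades.

# single record (6 rows of an fp_cohort) -> 6 x 17 matrix, movement rownames
.record_matrix <- function(record) {
  if (nrow(record) != 6L || anyDuplicated(record$movement) ||
      !setequal(record$movement, fp_movements())) {
    miss <- setdiff(fp_movements(), record$movement)
    if (length(miss)) {
      stop("record is missing movement(s): ", paste(miss, collapse = ", "))
    }
    stop("a record must consist of exactly one frame per movement")
  }
  m <- as.matrix(record[, fau_cols()])
  rownames(m) <- record$movement
  m[fp_movements(), , drop = FALSE]
}

#' Animation symmetry indices of one record
#'
#' For each of the six movements (rest included) and each of the six
#' left/right FAU pairs, the ASI measures how asymmetric the activation is.
#' The default index is the unnormalized absolute asymmetry
#' `|left - right|`; `normalize = TRUE` uses the relative form
#' `|left - right| / (left + right + eps)`.
#'
#' @param record One record: the 6 rows of an `fp_cohort` belonging to one
#'   `record_id`.
#' @param normalize Use the relative (ratio) index instead of the absolute
#'   difference.
#' @param eps Stabilizer for the normalized form.
#' @return Named numeric vector of 36 non-negative values,
#'   `asi_<movement>_<left>_<right>`, movements in canonical order.
#' @export
compute_asis <- function(record, normalize = FALSE, eps = 1e-8) {
  m <- .record_matrix(record)
  pairs <- fau_pairs()
  out <- numeric(0)
  for (mv in fp_movements()) {
    l <- m[mv, pairs$left]
    r <- m[mv, pairs$right]
    asi <- abs(l - r)
    if (normalize) asi <- asi / (l + r + eps)
    names(asi) <- sprintf("asi_%s_%d_%d", mv, pairs$left, pairs$right)
    out <- c(out, asi)
  }
  out
}

#' Facial-function grades of one record
#'
#' Each grade is the signed change of a movement-affected FAU from its
#' resting value (movement minus rest); the sign carries the direction of
#' activation. Eleven grades: two per movement for smiling, eye closure,
#' eyebrow raising and cheek blowing, three for whistling.
#'
#' @inheritParams compute_asis
#' @return Named numeric vector of 11 values in [-1, 1],
#'   `grade_<movement>_<fau>`.
#' @export
compute_grades <- function(record) {
  m <- .record_matrix(record)
  gs <- grade_schema()
  vals <- m[cbind(gs$movement, sprintf("FAU%d", gs$fau))] -
    m[cbind(rep("rest", nrow(gs)), sprintf("FAU%d", gs$fau))]
  names(vals) <- sprintf("grade_%s_%d", gs$movement, gs$fau)
  vals
}

#' Classifier feature vector of one record
#'
#' Concatenates the 30 non-rest ASIs and the 11 grades in the canonical
#' schema order ([feature_schema()]): per movement, ASIs before grades.
#'
#' @inheritParams compute_asis
#' @return Named numeric vector of length 41.
#' @export
build_feature_vector <- function(record, normalize = FALSE) {
  asis <- compute_asis(record, normalize = normalize)
  grades <- compute_grades(record)
  sch <- feature_schema()
  out <- c(asis, grades)[sch$name]
  if (anyNA(out)) stop("internal schema mismatch in feature vector")
  out
}

#' Transform a cohort into the labeled 41-feature table
#'
#' Applies [build_feature_vector()] to every record of a cohort.
#'
#' @param cohort An `fp_cohort` data frame.
#' @param normalize Passed to [compute_asis()].
#' @return Data frame with columns `record_id`, `label` and the 41 feature
#'   columns of [feature_schema()], one row per record.
#' @export
extract_features <- function(cohort, normalize = FALSE) {
  validate_cohort(cohort)
  sch <- feature_schema()
  if (nrow(cohort) == 0) {
    out <- as.data.frame(matrix(numeric(0), ncol = 41,
                                dimnames = list(NULL, sch$name)))
    return(cbind(data.frame(record_id = character(0), label = character(0)),
                 out))
  }
  # vectorized: reshape to one wide row per record, then index columns
  ids <- unique(cohort$record_id)
  fc <- fau_cols()
  wide <- array(NA_real_, dim = c(length(ids), 6, 17),
                dimnames = list(ids, fp_movements(), fc))
  for (mv in fp_movements()) {
    sub <- cohort[cohort$movement == mv, , drop = FALSE]
    wide[match(sub$record_id, ids), mv, ] <- as.matrix(sub[fc])
  }
  pairs <- fau_pairs()
  feats <- matrix(NA_real_, nrow = length(ids), ncol = nrow(sch),
                  dimnames = list(ids, sch$name))
  for (j in seq_len(nrow(sch))) {
    mv <- sch$movement[j]
    if (sch$kind[j] == "asi") {
      l <- wide[, mv, pairs$left[sch$pair[j]]]
      r <- wide[, mv, pairs$right[sch$pair[j]]]
      v <- abs(l - r)
      if (normalize) v <- v / (l + r + 1e-8)
    } else {
      v <- wide[, mv, sch$fau[j]] - wide[, "rest", sch$fau[j]]
    }
    feats[, j] <- v
  }
  labels <- cohort$label[match(ids, cohort$record_id)]
  out <- cbind(data.frame(record_id = ids, label = labels,
                          stringsAsFactors = FALSE),
               as.data.frame(feats, row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Extract one movement's feature subset from a feature table
#'
#' @param features Feature table from [extract_features()].
#' @param movement One of the five voluntary movements.
#' @return The subset of feature columns for that movement (6 ASIs + its
#'   grades; 8 columns, 9 for whistling).
#' @export
movement_feature_subset <- function(features, movement) {
  cols <- movement_feature_names(movement)
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  features[, cols, drop = FALSE]
}
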