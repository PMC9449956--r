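# Canonical schema: movements, class labels, FAU pairings and the derived
# feature layout. Everything downstream (generator, feature transform,
# classifiers) reads these definitions rather than hard-coding counts.

#' Canonical movement names
#'
#' The six facial states captured per session, in canonical order. `rest`
#' is the reference state; the remaining five are the voluntary movements
#' that get a dedicated first-level classifier.
#'
#' @return Character vector of length 6.
#' @export
fp_movements <- function() {
  c("rest", "smiling", "eye_closure", "eyebrow_raise", "cheek_blow", "whistle")
}

# movement order used for feature layout (rest carries no classifier features)
fp_classifier_movements <- function() {
  c("smiling", "eye_closure", "eyebrow_raise", "cheek_blow", "whistle")
}

#' Severity class labels
#'
#' The seven facial-palsy categories: normal plus mild/moderate/severe for
#' the left and right sides.
#'
#' @return Character vector `c("N","L_MI","L_MO","L_S","R_MI","R_MO","R_S")`.
#' @export
fp_classes <- function() {
  c("N", "L_MI", "L_MO", "L_S", "R_MI", "R_MO", "R_S")
}

.label_table <- function() {
  data.frame(
    symbol   = fp_classes(),
    side     = c("none", "left", "left", "left", "right", "right", "right"),
    severity = c("none", "mild", "moderate", "severe",
                 "mild", "moderate", "severe"),
    stringsAsFactors = FALSE
  )
}

#' Decompose a class label into side and severity
#'
#' The label set is a bijection between symbols and (side, severity) pairs;
#' `N` maps to (none, none).
#'
#' @param symbol Character vector of class symbols.
#' @return Data frame with columns `symbol`, `side`, `severity`.
#' @export
#' @examples
#' label_info("R_MO")
label_info <- function(symbol) {
  tab <- .label_table()
  idx <- match(symbol, tab$symbol)
  if (anyNA(idx)) {
    stop("unknown class label(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}

#' Build a class label from side and severity
#'
#' @param side One of "none", "left", "right".
#' @param severity One of "none", "mild", "moderate", "severe".
#' @return The class symbol.
#' @export
make_label <- function(side, severity) {
  tab <- .label_table()
  idx <- which(tab$side == side & tab$severity == severity)
  if (length(idx) != 1L) {
    stop("no class label for side='", side, "', severity='", severity, "'")
  }
  tab$symbol[idx]
}

#' Left/right FAU pairings
#'
#' The six anatomically paired facial animation units used for symmetry
#' analysis. Even indices are the left-side member. FAU14 (lip pucker) is
#' midline and unpaired; FAU1, FAU12, FAU13 and FAU15 are captured but not
#' used by the classifier features.
#'
#' @return Data frame with columns `pair` (1..6), `left`, `right` (FAU
#'   indices) and `name`.
#' @export
fau_pairs <- function() {
  data.frame(
    pair  = 1:6,
    left  = c(2L, 4L, 6L, 8L, 10L, 16L),
    right = c(3L, 5L, 7L, 9L, 11L, 17L),
    name  = c("eye_closure", "eyebrow_raiser", "lip_corner_puller",
              "lip_corner_depressor", "lower_lip_depressor", "cheek_puff"),
    stringsAsFactors = FALSE
  )
}

# FAUs whose movement-vs-rest difference defines the facial-function grades:
# the most affected units per movement (2 each; 3 for whistling, which also
# engages the midline lip pucker FAU14).
grade_schema <- function() {
  data.frame(
    movement = c("smiling", "smiling",
                 "eye_closure", "eye_closure",
                 "eyebrow_raise", "eyebrow_raise",
                 "cheek_blow", "cheek_blow",
                 "whistle", "whistle", "whistle"),
    fau = c(6L, 7L, 2L, 3L, 4L, 5L, 16L, 17L, 14L, 16L, 17L),
    stringsAsFactors = FALSE
  )
}

#' Classifier feature schema
#'
#' The fixed layout of the 41 classifier-input features: for each of the
#' five voluntary movements (canonical order smiling, eye_closure,
#' eyebrow_raise, cheek_blow, whistle) its 6 animation symmetry indices
#' (ASIs) followed by its rest-difference grades (2 per movement, 3 for
#' whistling). Rest-state ASIs are computed but excluded from the
#' classifier input.
#'
#' @return Data frame with one row per feature: `name`, `movement`,
#'   `kind` ("asi" or "grade"), `pair` (ASI rows), `fau` (grade rows).
#' @export
feature_schema <- function() {
  pairs <- fau_pairs()
  gs <- grade_schema()
  out <- list()
  # grade movement order follows the canonical movement order
  for (m in fp_classifier_movements()) {
    asi <- data.frame(
      name = sprintf("asi_%s_%d_%d", m, pairs$left, pairs$right),
      movement = m, kind = "asi", pair = pairs$pair, fau = NA_integer_,
      stringsAsFactors = FALSE
    )
    gf <- gs$fau[gs$movement == m]
    grd <- data.frame(
      name = sprintf("grade_%s_%d", m, gf),
      movement = m, kind = "grade", pair = NA_integer_, fau = gf,
      stringsAsFactors = FALSE
    )
    out[[m]] <- rbind(asi, grd)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Feature names for one movement's classifier
#'
#' @param movement One of the five voluntary movements.
#' @return Character vector of feature names (8, or 9 for whistling).
#' @export
movement_feature_names <- function(movement) {
  movement <- match.arg(movement, fp_classifier_movements())
  sch <- feature_schema()
  sch$name[sch$movement == movement]
}

# (movement, FAU) pairs feeding the symmetry-analysis module: the 12 paired
# FAUs in each of the 6 states.
.symmetry_fau_set <- function() {
  pairs <- fau_pairs()
  faus <- sort(c(pairs$left, pairs$right))
  expand.grid(movement = fp_movements(), fau = faus,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# (movement, FAU) pairs feeding the grading module: the graded movement FAUs
# plus their rest-state counterparts (deduplicated).
.grading_fau_set <- function() {
  gs <- grade_schema()
  rest <- data.frame(movement = "rest", fau = sort(unique(gs$fau)),
                     stringsAsFactors = FALSE)
  unique(rbind(gs[, c("movement", "fau")], rest))
}

#' Count the raw FAUs consumed by the feature-transformation modules
#'
#' Computed from the schema, not hard-coded: the symmetry set is the 12
#' paired FAUs in all 6 states (72), the grading set is the 11 graded
#' movement FAUs plus their 9 distinct rest counterparts (20), and their
#' union has 74 members (only FAU14 at rest and during whistling is unique
#' to the grading set).
#'
#' @param set Which set to count: `"union"` (default), `"symmetry"` or
#'   `"grading"`.
#' @return Integer count of distinct (movement, FAU) inputs.
#' @export
#' @examples
#' selected_fau_count()            # 74
#' selected_fau_count("symmetry")  # 72
#' selected_fau_count("grading")   # 20
selected_fau_count <- function(set = c("union", "symmetry", "grading")) {
  set <- match.arg(set)
  s1 <- .symmetry_fau_set()
  s2 <- .grading_fau_set()
  tagged <- switch(set,
    symmetry = s1,
    grading  = s2,
    union    = unique(rbind(s1, s2))
  )
  nrow(tagged)
}

# internal: FAU column names in record tables
fau_cols <- function() sprintf("FAU%d", 1:17)
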