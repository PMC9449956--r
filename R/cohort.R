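# Synthetic cohort generation and CSV record I/O.
#
# A cohort is a long-format data frame (class "fp_cohort"): one row per
# (record, movement), columns record_id, label, movement, FAU1..FAU17.
# Each record is one full session — all six movement states — and carries
# a single severity label.

#' Default activation template
#'
#' Baseline FAU activation for each movement in a healthy subject. Rows are
#' the six movements, columns FAU1..FAU17. Rest is all zeros; each
#' voluntary movement activates its primary paired units at 0.8, with
#' smaller co-activations of mechanically coupled units, and whistling
#' activates the midline lip pucker (FAU14) at 0.7 plus the cheek units
#' at 0.5.
#'
#' @return 6 x 17 numeric matrix with movement rownames and FAU colnames.
#' @export
default_activation_template <- function() {
  tmpl <- matrix(0, nrow = 6, ncol = 17,
                 dimnames = list(fp_movements(), fau_cols()))
  tmpl["smiling", c("FAU6", "FAU7")] <- 0.8
  tmpl["smiling", c("FAU8", "FAU9")] <- 0.3
  tmpl["smiling", c("FAU10", "FAU11")] <- 0.2
  tmpl["eye_closure", c("FAU2", "FAU3")] <- 0.8
  tmpl["eyebrow_raise", c("FAU4", "FAU5")] <- 0.8
  tmpl["cheek_blow", c("FAU16", "FAU17")] <- 0.8
  tmpl["whistle", "FAU14"] <- 0.7
  tmpl["whistle", c("FAU16", "FAU17")] <- 0.5
  tmpl["whistle", c("FAU6", "FAU7")] <- 0.2
  tmpl
}

#' Cohort generator configuration
#'
#' @param class_counts Named integer vector: records to generate per class
#'   symbol. Defaults to the study's class frequencies (normal class at its
#'   post-undersampling size of 289).
#' @param attenuation Named numeric vector mapping severity to the
#'   multiplicative activation factor retained on the paralyzed side. Must
#'   be strictly decreasing with severity and lie in [0, 1].
#' @param activation_template 6 x 17 matrix of baseline activations in
#'   [0, 1]; see [default_activation_template()].
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise applied to every FAU value (then clipped to [0, 1]).
#' @param seed Integer RNG seed; the cohort is fully reproducible given it.
#' @return A list of class `"fp_cohort_config"`.
#' @export
cohort_config <- function(class_counts = c(N = 289, L_MI = 127, L_MO = 0,
                                           L_S = 0, R_MI = 35, R_MO = 177,
                                           R_S = 36),
                          attenuation = c(none = 1.0, mild = 0.65,
                                          moderate = 0.35, severe = 0.10),
                          activation_template = default_activation_template(),
                          noise_sd = 0.05,
                          seed = 1L) {
  if (is.null(names(class_counts)) ||
      !all(names(class_counts) %in% fp_classes())) {
    stop("class_counts must be named with class symbols from fp_classes()")
  }
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  req <- c("none", "mild", "moderate", "severe")
  if (!all(req %in% names(attenuation))) {
    stop("attenuation must name levels none, mild, moderate, severe")
  }
  attenuation <- attenuation[req]
  if (any(attenuation < 0 | attenuation > 1)) {
    stop("attenuation factors must lie in [0, 1]")
  }
  if (any(diff(attenuation) >= 0)) {
    stop("attenuation must be strictly decreasing with severity")
  }
  stopifnot(is.matrix(activation_template),
            nrow(activation_template) == 6, ncol(activation_template) == 17)
  if (any(activation_template < 0 | activation_template > 1)) {
    stop("activation template values must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(class_counts = class_counts,
                 attenuation = attenuation,
                 activation_template = activation_template,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fp_cohort_config")
}

#' Generate a synthetic facial-palsy cohort
#'
#' Emulates the statistical structure the classifier assumes: for a record
#' with paralyzed side s and severity v, every paired FAU on side s that a
#' movement activates is drawn around `attenuation[v]` times its template
#' activation, while the contralateral member keeps the full activation.
#' The midline FAU14 is attenuated halfway, by `(1 + attenuation[v]) / 2`,
#' since both sides contribute to the pucker. Rest-state values sit near 0.
#' Gaussian noise of sd `noise_sd` is added and values are clipped to
#' [0, 1].
#'
#' @param config An [cohort_config()] object.
#' @return An `fp_cohort` data frame: one row per (record, movement),
#'   columns `record_id`, `label`, `movement`, `FAU1`..`FAU17`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(class_counts = c(N = 3, R_S = 2)))
#' table(cohort$label) / 6
generate_cohort <- function(config) {
  stopifnot(inherits(config, "fp_cohort_config"))
  counts <- config$class_counts[config$class_counts > 0]
  tmpl <- config$activation_template
  pairs <- fau_pairs()
  movements <- fp_movements()

  blocks <- list()
  for (cls in names(counts)) {
    n <- counts[[cls]]
    info <- label_info(cls)
    att <- config$attenuation[[if (info$severity == "none") "none"
                               else info$severity]]
    mean_mat <- tmpl  # 6 x 17 per-record mean activations
    if (info$side != "none") {
      side_faus <- if (info$side == "left") pairs$left else pairs$right
      mean_mat[, side_faus] <- mean_mat[, side_faus] * att
      mean_mat[, "FAU14"] <- mean_mat[, "FAU14"] * (1 + att) / 2
    }
    ids <- sprintf("%s_%04d", cls, seq_len(n))
    block <- data.frame(
      record_id = rep(ids, each = 6L),
      label = cls,
      movement = rep(movements, times = n),
      stringsAsFactors = FALSE
    )
    vals <- mean_mat[rep(seq_len(6), times = n), , drop = FALSE]
    blocks[[cls]] <- cbind(block, as.data.frame(vals, row.names = FALSE))
  }
  cohort <- do.call(rbind, blocks)
  rownames(cohort) <- NULL

  if (nrow(cohort) > 0 && config$noise_sd > 0) {
    fc <- fau_cols()
    noise <- with_seed(config$seed,
      matrix(stats::rnorm(nrow(cohort) * 17, sd = config$noise_sd),
             nrow = nrow(cohort)))
    cohort[fc] <- pmin(pmax(as.matrix(cohort[fc]) + noise, 0), 1)
  }
  class(cohort) <- c("fp_cohort", "data.frame")
  cohort
}

#' Write cohort records to CSV
#'
#' One row per (record, movement); header
#' `record_id,label,movement,FAU1,...,FAU17`. Full numeric precision is
#' kept so that a write/load round trip reproduces the records.
#'
#' @param records An `fp_cohort` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  validate_cohort(records)
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load cohort records from CSV
#'
#' Validates the file against the record contract: required columns, known
#' labels and movements, numeric FAU values, all six movements present
#' exactly once per record. In strict mode (default) FAU values outside
#' [0, 1] are an error; in lenient mode they are clipped with a warning.
#'
#' @param path CSV file path.
#' @param strict Error on out-of-range FAU values (default `TRUE`).
#' @return An `fp_cohort` data frame (empty if the file has only a header).
#' @export
load_records <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "label", "movement", fau_cols())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  if (nrow(df) == 0) {
    class(df) <- c("fp_cohort", "data.frame")
    return(df)
  }
  bad_label <- !df$label %in% fp_classes()
  if (any(bad_label)) {
    stop("unknown label '", df$label[which(bad_label)[1]], "' at row ",
         which(bad_label)[1])
  }
  bad_mv <- !df$movement %in% fp_movements()
  if (any(bad_mv)) {
    stop("unknown movement '", df$movement[which(bad_mv)[1]], "' at row ",
         which(bad_mv)[1])
  }
  fc <- fau_cols()
  for (col in fc) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("non-numeric value in ", col, " at row ",
           if (is.na(bad)) 1L else bad)
    }
  }
  vals <- as.matrix(df[fc])
  if (anyNA(vals)) {
    stop("non-numeric or missing FAU value at row ",
         which(rowSums(is.na(vals)) > 0)[1])
  }
  out_of_range <- vals < 0 | vals > 1
  if (any(out_of_range)) {
    row1 <- which(rowSums(out_of_range) > 0)[1]
    if (strict) {
      stop("FAU value outside [0, 1] at row ", row1)
    }
    warning("clipping ", sum(out_of_range), " FAU value(s) to [0, 1]")
    df[fc] <- pmin(pmax(vals, 0), 1)
  }
  class(df) <- c("fp_cohort", "data.frame")
  validate_cohort(df)
  df
}

#' Validate the cohort record contract
#'
#' @param records An `fp_cohort` (or plain) data frame of records.
#' @return `records`, invisibly; errors name the offending record.
#' @export
validate_cohort <- function(records) {
  need <- c("record_id", "label", "movement", fau_cols())
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) return(invisible(records))
  by_rec <- split(records$movement, records$record_id)
  for (id in names(by_rec)) {
    mv <- by_rec[[id]]
    if (anyDuplicated(mv)) {
      stop("record '", id, "' has duplicated movement(s): ",
           paste(unique(mv[duplicated(mv)]), collapse = ", "))
    }
    miss <- setdiff(fp_movements(), mv)
    if (length(miss)) {
      stop("record '", id, "' is missing movement(s): ",
           paste(miss, collapse = ", "))
    }
  }
  labs <- tapply(records$label, records$record_id,
                 function(l) length(unique(l)))
  if (any(labs > 1)) {
    stop("record '", names(labs)[labs > 1][1], "' has conflicting labels")
  }
  invisible(records)
}
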