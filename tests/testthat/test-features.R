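test_that("ASIs measure pairwise left-right asymmetry", {
  cohort <- generate_cohort(cohort_config(class_counts = c(N = 1),
                                          noise_sd = 0))
  rec <- one_record(cohort)
  asis <- compute_asis(rec)
  expect_length(asis, 36)
  expect_true(all(asis == 0))  # symmetric record

  rec2 <- rec
  rec2[rec2$movement == "smiling", "FAU6"] <- 0.8
  rec2[rec2$movement == "smiling", "FAU7"] <- 0.2
  asis2 <- compute_asis(rec2)
  expect_equal(asis2[["asi_smiling_6_7"]], 0.6)
  expect_true(all(asis2 >= 0))
})

test_that("grades are signed movement-minus-rest differences", {
  cohort <- generate_cohort(cohort_config(class_counts = c(N = 1),
                                          noise_sd = 0))
  rec <- one_record(cohort)
  rec[, fau_cols()] <- rep(0.1, 17)[col(rec[, fau_cols()])]  # all frames flat
  grades <- compute_grades(rec)
  expect_length(grades, 11)
  expect_true(all(grades == 0))

  rec[rec$movement == "smiling", "FAU6"] <- 0.7
  rec[rec$movement == "rest", "FAU6"] <- 0.1
  grades2 <- compute_grades(rec)
  expect_equal(grades2[["grade_smiling_6"]], 0.6)
})

test_that("feature vector concatenates 30 non-rest ASIs and 11 grades", {
  cohort <- generate_cohort(cohort_config(class_counts = c(R_MO = 1),
                                          seed = 3))
  fv <- build_feature_vector(one_record(cohort))
  expect_length(fv, 41)
  expect_identical(names(fv), feature_schema()$name)
  expect_false(any(grepl("rest", names(fv))))

  # fully symmetric record whose movements equal rest -> zero vector
  flat <- one_record(generate_cohort(cohort_config(class_counts = c(N = 1),
                                                   noise_sd = 0)))
  flat[, fau_cols()] <- 0.2
  expect_equal(unname(build_feature_vector(flat)), rep(0, 41))
})

test_that("missing frames are reported", {
  cohort <- generate_cohort(cohort_config(class_counts = c(N = 1)))
  rec <- one_record(cohort)
  expect_error(compute_asis(rec[rec$movement != "rest", ]),
               "missing movement.*rest")
  expect_error(compute_grades(rec[rec$movement != "rest", ]),
               "missing movement.*rest")
})

test_that("ASIs are invariant to left/right swap and common shifts", {
  cohort <- generate_cohort(cohort_config(
    class_counts = c(L_MI = 5, R_S = 5), seed = 17))
  pairs <- fau_pairs()
  for (id in unique(cohort$record_id)[c(1, 6)]) {
    rec <- one_record(cohort, id)
    swapped <- rec
    for (p in seq_len(nrow(pairs))) {
      l <- sprintf("FAU%d", pairs$left[p]); r <- sprintf("FAU%d", pairs$right[p])
      swapped[[l]] <- rec[[r]]
      swapped[[r]] <- rec[[l]]
    }
    expect_equal(compute_asis(swapped), compute_asis(rec))

    shifted <- rec
    shifted[, fau_cols()] <- pmin(as.matrix(rec[, fau_cols()]) + 0.05, 1)
    keep <- as.matrix(rec[, fau_cols()]) + 0.05 <= 1  # only unclipped shifts
    if (all(keep)) {
      expect_equal(compute_asis(shifted), compute_asis(rec),
                   tolerance = 1e-12)
    }
  }
})

test_that("vectorized extraction matches an independent per-field oracle", {
  cohort <- generate_cohort(cohort_config(
    class_counts = c(N = 40, L_MI = 20, R_MI = 15, R_MO = 15, R_S = 10),
    seed = 23))
  feats <- extract_features(cohort)
  sch <- feature_schema()
  pairs <- fau_pairs()
  # brute-force oracle: look each value up straight from the table fields
  ids <- sample(unique(cohort$record_id), 100)
  for (id in ids) {
    rec <- cohort[cohort$record_id == id, ]
    row <- feats[feats$record_id == id, ]
    expected <- vapply(seq_len(nrow(sch)), function(j) {
      mv <- sch$movement[j]
      if (sch$kind[j] == "asi") {
        abs(rec[rec$movement == mv, sprintf("FAU%d", pairs$left[sch$pair[j]])] -
            rec[rec$movement == mv, sprintf("FAU%d", pairs$right[sch$pair[j]])])
      } else {
        rec[rec$movement == mv, sprintf("FAU%d", sch$fau[j])] -
          rec[rec$movement == "rest", sprintf("FAU%d", sch$fau[j])]
      }
    }, numeric(1))
    expect_equal(unname(unlist(row[sch$name])), expected, tolerance = 1e-12)
    # and the per-record path agrees with the vectorized path
    expect_equal(unname(build_feature_vector(rec)), expected,
                 tolerance = 1e-12)
  }
})

test_that("movement subsets have the schema arity", {
  feats <- small_features()
  expect_equal(ncol(movement_feature_subset(feats, "smiling")), 8)
  expect_equal(ncol(movement_feature_subset(feats, "whistle")), 9)
  expect_error(movement_feature_subset(feats[, 1:10], "whistle"),
               "lacks column")
})

test_that("normalized ASI variant is bounded and zero iff symmetric", {
  cohort <- generate_cohort(cohort_config(class_counts = c(R_S = 3),
                                          seed = 31))
  rec <- one_record(cohort)
  asis <- compute_asis(rec, normalize = TRUE)
  expect_true(all(asis >= 0 & asis <= 1))
  sym <- one_record(generate_cohort(cohort_config(class_counts = c(N = 1),
                                                  noise_sd = 0)))
  expect_true(all(compute_asis(sym, normalize = TRUE) == 0))
})
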