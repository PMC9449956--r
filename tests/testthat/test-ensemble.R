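test_that("combiner follows the documented decision rules", {
  expect_combiner <- function(votes, final, rationale, probs = NULL) {
    out <- combine_votes(votes, probs)
    expect_equal(out$final, final)
    expect_equal(out$rationale, rationale)
  }
  expect_combiner(c("R_MO", "R_MO", "R_MO", "N", "L_MI"), "R_MO", "majority")
  expect_combiner(c("N", "N", "R_S", "R_S", "L_MI"), "R_S", "tie_rule_a")

  mk_probs <- function(per_class) {
    lapply(1:5, function(i) {
      p <- per_class / 5
      p / sum(p) -> p
      p
    })
  }
  probs <- mk_probs(c(L_MI = 1.9, R_MO = 2.3, N = 0.5, R_MI = 0.2,
                      R_S = 0.1))
  expect_combiner(c("L_MI", "L_MI", "R_MO", "R_MO", "N"), "R_MO",
                  "tie_rule_b", probs)
  expect_combiner(c("N", "L_MI", "R_MI", "R_MO", "R_S"), "R_MO",
                  "prob_sum_fallback", probs)
  expect_error(combine_votes(c("N", "N", "N")), "exactly 5")
})

test_that("combiner matches a brute-force oracle on all vote multisets", {
  classes <- c("N", "L_MI", "R_MI", "R_MO", "R_S")
  # fixed distinct probability vectors, one per classifier
  set.seed(123)
  probs <- lapply(1:5, function(i) {
    p <- runif(5) + 0.1
    stats::setNames(p / sum(p), classes)
  })
  psum <- Reduce(`+`, probs)

  oracle <- function(votes) {
    counts <- table(votes)
    top <- max(counts)
    leaders <- names(counts)[counts == top]
    leaders <- leaders[order(match(leaders, classes))]
    if (top >= 3) return(leaders[1])
    if (top == 2 && length(leaders) == 1) return(leaders[1])
    if (top == 2) {
      if ("N" %in% leaders && length(leaders) == 2) {
        return(setdiff(leaders, "N"))
      }
      return(leaders[which.max(psum[leaders])])
    }
    names(psum)[which.max(psum[classes])]
  }

  # every multiset of 5 votes over the 5 classes, in several listing orders
  grids <- expand.grid(rep(list(classes), 5), stringsAsFactors = FALSE)
  seen <- character(0)
  for (i in seq_len(nrow(grids))) {
    votes <- as.character(grids[i, ])
    key <- paste(sort(votes), collapse = "|")
    out <- combine_votes(votes, probs)
    expect_equal(out$final, oracle(votes))
    expect_equal(sum(out$vote_counts), 5)
    if (!key %in% seen) {
      seen <- c(seen, key)
      # order invariance: a shuffled listing gives the same decision
      shuffled <- combine_votes(sample(votes), probs)
      expect_equal(shuffled$final, out$final)
    }
  }
  expect_equal(length(seen), choose(9, 4))  # 126 distinct multisets
  # all four rationale branches are reachable
  rats <- vapply(seq_len(nrow(grids)), function(i)
    combine_votes(as.character(grids[i, ]), probs)$rationale, character(1))
  expect_setequal(unique(rats), c("majority", "plurality", "tie_rule_a",
                                  "tie_rule_b", "prob_sum_fallback"))
})

test_that("stratified split preserves class proportions within one sample", {
  cohort <- generate_cohort(cohort_config(
    class_counts = c(N = 289, L_MI = 127, R_MI = 35, R_MO = 177, R_S = 36),
    seed = 14))
  feats <- extract_features(cohort)
  parts <- stratified_split(feats, ratio = 0.8, seed = 6)
  expect_true(nrow(parts$test) %in% c(132, 133))
  expect_equal(nrow(parts$train) + nrow(parts$test), 664)
  expect_length(intersect(parts$train$record_id, parts$test$record_id), 0)
  expect_setequal(c(parts$train$record_id, parts$test$record_id),
                  feats$record_id)
  global <- table(feats$label) / nrow(feats)
  for (part in parts) {
    got <- table(factor(part$label, names(global)))
    expect_true(all(abs(got - global * nrow(part)) <= 1 + 1e-9))
  }
  # a class absent from the input is absent from both parts
  expect_false("L_S" %in% c(parts$train$label, parts$test$label))
  expect_error(stratified_split(feats[c(1:10, which(feats$label == "R_S")[1]), ]),
               "fewer than 2")
})

test_that("ensemble separates a zero-noise cohort perfectly", {
  cohort <- generate_cohort(cohort_config(
    class_counts = c(N = 25, L_MI = 15, R_MI = 15, R_MO = 15, R_S = 15),
    noise_sd = 0, seed = 10))
  feats <- extract_features(cohort)
  parts <- stratified_split(feats, seed = 2)
  model <- fp_ensemble(parts$train, C_grid = 10, gamma_grid = 0.5, seed = 3)
  pred <- predict(model, parts$test)
  expect_equal(mean(pred == parts$test$label), 1.0)
})

test_that("the full pipeline is deterministic and reports 41 features", {
  cohort <- generate_cohort(cohort_config(
    class_counts = c(N = 40, L_MI = 15, R_MI = 10, R_MO = 15, R_S = 10),
    seed = 19))
  cfg <- pipeline_config(seed = 5, undersample_to = 25,
                         C_grid = c(1, 100), gamma_grid = c(0.1, 1))
  r1 <- run_pipeline(cohort, cfg)
  r2 <- run_pipeline(cohort, cfg)
  expect_identical(unclass(r1$confusion), unclass(r2$confusion))
  expect_identical(r1$hyperparameters, r2$hyperparameters)
  expect_equal(sum(r1$confusion), r1$sizes$test)
  expect_equal(r1$sizes$after_undersampling, 75)
  # classifiers consume the 41-feature schema
  n_feats <- sum(vapply(r1$model$classifiers,
                        function(c) length(c$feature_names), integer(1)))
  expect_equal(n_feats, 41)
  expect_s3_class(r1$model, "fp_ensemble")
  expect_equal(nrow(r1$classifier_metrics), 10)  # 5 movements x 2 modes
})

test_that("pipeline errors carry the failing stage", {
  bad <- generate_cohort(cohort_config(class_counts = c(N = 10, R_S = 1),
                                       seed = 2))
  expect_error(run_pipeline(bad, pipeline_config(undersample = FALSE)),
               "stage \\[stratified split\\]")
})
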