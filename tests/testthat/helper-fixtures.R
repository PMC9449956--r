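# Shared fixture builders. Cohorts are generated in code at test time;
# moderately expensive shared objects are memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small five-class cohort with clear severity structure
small_cohort <- function(noise = 0.05, seed = 11) {
  generate_cohort(cohort_config(
    class_counts = c(N = 30, L_MI = 15, R_MI = 10, R_MO = 15, R_S = 10),
    noise_sd = noise, seed = seed))
}

small_features <- function() {
  cached("small_features", function() extract_features(small_cohort()))
}

# reference confusion matrix shipped as a plain-text fixture
reference_cm <- function() {
  read_confusion_matrix(system.file("extdata",
                                    "reference_confusion_matrix.csv",
                                    package = "faupalsy"))
}

# one record (6 frames) pulled out of a cohort
one_record <- function(cohort, id = cohort$record_id[1]) {
  cohort[cohort$record_id == id, , drop = FALSE]
}
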