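# Shared, lazily-built synthetic fixtures. Building the default cohort costs
# ~1 min, so it is computed once per test session and reused by the feature,
# screening, ensemble and acceptance suites. Seeds are the package defaults,
# fixed a priori.

.pf_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.pf_cache[[key]])) .pf_cache[[key]] <- builder()
  .pf_cache[[key]]
}

# full-scale 14-subject cohort driven by the packaged difficulty table
default_cohort <- function() {
  cached("cohort", function() simulate_cohort(sim_plan(n_subjects = 14, seed = 1)))
}

default_cohort_fm <- function() {
  cached("cohort_fm", function() cohort_features(default_cohort()))
}

# one small subject (six 150 s segments: long enough for the 2-min spectral
# HRV buffer to fill) for unit tests
mini_set <- function() {
  cached("mini_set", function() {
    sched <- data.frame(behavior = behavior_labels(), duration_s = 150)
    plan <- sim_plan(n_subjects = 1, schedule = sched, seed = 11,
                     difficulty_table = NULL, jitter_sdlog = 0)
    simulate_cohort(plan)[[1]]
  })
}

mini_clean <- function() {
  cached("mini_clean", function() preprocess_recording_set(mini_set()))
}

mini_fm <- function() {
  cached("mini_fm", function() fuse_features(mini_clean()))
}

# small exchangeable cohorts (mean-difficulty profiles, no per-subject
# ratings) at two inter-subject jitter levels, for the LOO-degradation check
jitter_cohort_fm <- function(jitter) {
  key <- paste0("jitter_fm_", jitter)
  cached(key, function() {
    plan <- sim_plan(n_subjects = 6, seed = 5, difficulty_table = NULL,
                     jitter_sdlog = jitter)
    cohort_features(simulate_cohort(plan))
  })
}

# well-separated Gaussian-blob feature rows for classifier unit tests
blob_data <- function(n_per = 40, k = 3, p = 5, sep = 6, seed = 99) {
  set.seed(seed)
  labels <- behavior_labels()[seq_len(k)]
  X <- do.call(rbind, lapply(seq_len(k), function(c) {
    centers <- rnorm(p, 0, 1) + sep * c
    matrix(rnorm(n_per * p, rep(centers, each = n_per), 1), n_per, p)
  }))
  colnames(X) <- paste0("f", seq_len(p))
  df <- as.data.frame(X)
  df$label <- rep(labels, each = n_per)
  df
}
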