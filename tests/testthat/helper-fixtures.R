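# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# A small but complete cohort (2 patients x 12 ICs) with features.
tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- synthetic_config(seed = 42, n_patients = 3, ics_per_patient = 12)
    .fixture_env$tiny <- generate_cohort(cfg)
  }
  .fixture_env$tiny
}

tiny_features <- function() {
  if (is.null(.fixture_env$tiny_cf))
    .fixture_env$tiny_cf <- cohort_features(tiny_cohort())
  .fixture_env$tiny_cf
}

# The evaluation-scale cohort (10 patients x 100 ICs, separation 1, seed 1)
# with its leave-one-patient-out reports; built once and shared by the
# acceptance tests.
eval_artifacts <- function() {
  if (is.null(.fixture_env$eval)) {
    cohort <- generate_cohort(synthetic_config(seed = 1))
    cf <- cohort_features(cohort)
    cache <- new.env(parent = emptyenv())
    rep_fused <- loocv(cf, mode = "fused", dl_cache = cache, seed = 1)
    rep_cnn3 <- loocv(cf, mode = "cnn3", dl_cache = cache, seed = 1)
    abl <- ablation_suite(cf, seed = 1, dl_cache = cache)
    .fixture_env$eval <- list(cohort = cohort, cf = cf, fused = rep_fused,
                              cnn3 = rep_cnn3, ablation = abl)
  }
  .fixture_env$eval
}

# Deterministic random activation masks for clustering oracles.
random_mask <- function(seed, max_dim = 40L, density = NULL) {
  set.seed(seed)
  h <- sample(8:max_dim, 1); w <- sample(8:max_dim, 1)
  if (is.null(density)) density <- runif(1, 0.05, 0.5)
  matrix(runif(h * w) < density, h, w)
}
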