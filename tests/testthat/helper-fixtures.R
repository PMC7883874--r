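# Shared fixtures, built once per test run and memoised in this
# environment (test files share the process).
.fixtures <- new.env(parent = emptyenv())

# A small but complete scene: 2 blocks x 6 treatments, one season with one
# harvest, reduced point densities.  Exercises every stage quickly.
small_scene <- function() {
  if (is.null(.fixtures$small_scene)) {
    cfg <- sim_config(seed = 11, n_replicates = 2,
                      years = default_years()[2], harvests_per_year = 1,
                      point_density = 400, ground_density = 700,
                      exclusions = "none")
    .fixtures$small_scene <- simulate_experiment(cfg)
  }
  .fixtures$small_scene
}

small_features <- function() {
  if (is.null(.fixtures$small_features)) {
    .fixtures$small_features <- extract_features(small_scene())
  }
  .fixtures$small_features
}

# The default two-year experiment, truth table only (fast).
default_truth <- function() {
  if (is.null(.fixtures$default_truth)) {
    .fixtures$default_truth <- simulate_experiment(
      sim_config(seed = 1), generate_clouds = FALSE,
      generate_rasters = FALSE)$truth
  }
  .fixtures$default_truth
}

# Full default-scene pipeline at 25 splits for the FM response, shared by
# the acceptance checks.  Heavy (several minutes); built on first use.
default_pipeline_fm <- function() {
  if (is.null(.fixtures$default_pipeline_fm)) {
    .fixtures$default_pipeline_fm <- run_pipeline(
      sim_config(seed = 1), responses = "FM",
      variants = c("CSH", "MS", "Fusion"), n_splits = 25)
  }
  .fixtures$default_pipeline_fm
}

# Regression design with a planted signal: k_informative standardised
# predictors drive y at the given signal-to-noise ratio, the rest is noise.
planted_design <- function(n = 140, p = 50, k_informative = 3, snr = 3,
                           seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- sprintf("x%02d", seq_len(p))
  signal <- rowSums(x[, seq_len(k_informative), drop = FALSE])
  noise_sd <- sd(signal) / snr
  y <- signal + rnorm(n, 0, noise_sd)
  list(x = x, y = y, informative = names(x)[seq_len(k_informative)])
}
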