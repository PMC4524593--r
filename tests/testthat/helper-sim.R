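# Shared fixtures: a desk-scale simulation config and a cached preprocessed
# subject reused across test files (generation is deterministic, so caching
# only saves time).

small_cfg <- function(seed = 42, ...) {
  args <- list(grid_dims = c(12, 12, 12), trs_per_run = 90,
               n_signal_voxels = 300, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

tiny_cfg <- function(seed = 1, ...) {
  small_cfg(seed = seed, grid_dims = c(10, 10, 10), trs_per_run = 30,
            n_signal_voxels = 60, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_subject <- function() {
  if (is.null(.fixture_cache$sd)) {
    .fixture_cache$sd <- generate_subject(small_cfg())
    .fixture_cache$pp <- preprocess_subject(.fixture_cache$sd$subject)
  }
  list(sd = .fixture_cache$sd, pp = .fixture_cache$pp)
}

# Wilcoxon/Mann-Whitney AUC of a score for recovering a logical truth vector.
rank_auc <- function(score, truth) {
  r <- rank(score)
  (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
}

# A minimal raw run with white noise around the baseline.
noise_run <- function(T = 30, dims = c(10, 10, 10), seed = 1,
                      condition = "neutral", repetition = 1,
                      motion_sd = 0.05) {
  grid <- voxel_grid(dims)
  set.seed(seed)
  arr <- array(1000 + 10 * rnorm(prod(dims) * T), dim = c(dims, T))
  bold_run(arr, grid, 2, condition, repetition,
           generate_motion(T, motion_sd, seed = seed + 1))
}
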