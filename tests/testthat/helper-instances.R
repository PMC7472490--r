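# Shared fixtures, built in code. Expensive ones are memoised so several
# test files can reuse them without recomputation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# The standard synthetic instance: 4 markers (12 channels), 2 shared
# harmonics, latent rank 4, 200 frames (4 cycles of 50), one 20-frame gap per
# marker, no noise.
standard_instance <- function() {
  memo("standard_instance", {
    cfg <- gait_sim_config(
      n_markers = 4, n_frames = 200, frame_rate = 240, cycle_frames = 50,
      n_harmonics = 2, latent_rank = 4, rng_seed = 11
    )
    sim <- generate_trajectories(cfg)
    vals <- sim$truth$values
    obs <- matrix(TRUE, 200, 12)
    starts <- c(30, 80, 120, 160)
    for (k in 1:4) {
      rows <- starts[k] + 0:19
      ch <- marker_channels(k)
      vals[rows, ch] <- NA_real_
      obs[rows, ch] <- FALSE
    }
    list(
      truth = sim$truth,
      gapped = trajectory_matrix(vals, 240, sim$truth$marker_names),
      mask = observation_mask(obs),
      weights = spectral_weights(200, threshold_bin = 10),
      sim_cfg = cfg
    )
  })
}

# Relative error restricted to originally-missing entries.
missing_rel_error <- function(completed, truth, mask) {
  miss <- !mask$observed
  fro_miss <- function(m) sqrt(sum(m[miss]^2))
  fro_miss(completed$values - truth$values) / fro_miss(truth$values)
}

# A small random trajectory with marker-atomic gaps, for structural tests.
random_gapped_tm <- function(seed, n = 30, m = 2) {
  set.seed(seed)
  vals <- matrix(rnorm(n * 3 * m, sd = 10), n, 3 * m)
  obs <- matrix(TRUE, n, 3 * m)
  for (k in seq_len(m)) {
    len <- sample(3:8, 1)
    start <- sample(seq_len(n - len), 1)
    ch <- marker_channels(k)
    obs[start + seq_len(len) - 1L, ch] <- FALSE
    vals[start + seq_len(len) - 1L, ch] <- NA_real_
  }
  list(tm = trajectory_matrix(vals, 100, sprintf("M%d", seq_len(m))),
       mask = observation_mask(obs))
}

# The scaled repeated-gap experiment shared by the comparative acceptance
# checks: 37 markers, 10 cycles of 60 frames, 20 repetitions, default gap
# protocol (5-20 gaps of 10-50% of a cycle).
experiment_sim_cfg <- function() {
  gait_sim_config(n_markers = 37, n_frames = 600, frame_rate = 240,
                  cycle_frames = 60, rng_seed = 100)
}

experiment_solver_cfg <- function() {
  solver_config(lambda = 1e4, max_iter = 200, tol = 1e-5)
}

experiment_full <- function() {
  memo("experiment_full", {
    run_experiment(experiment_sim_cfg(), gap_spec(repetitions = 20, rng_seed = 200),
                   solver_cfg = experiment_solver_cfg())
  })
}

experiment_subset <- function() {
  memo("experiment_subset", {
    run_experiment(experiment_sim_cfg(), gap_spec(repetitions = 20, rng_seed = 200),
                   marker_subset = sprintf("M%02d", seq(1, 31, 3)),
                   solver_cfg = experiment_solver_cfg())
  })
}
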