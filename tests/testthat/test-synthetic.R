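test_that("generator invariants are enforced", {
  expect_error(gait_sim_config(latent_rank = 5, n_harmonics = 2), "latent_rank")
  expect_error(gait_sim_config(cycle_frames = 10, n_harmonics = 4), "cycle_frames")
})

test_that("noiseless output has the configured rank, spectral support and periodicity", {
  cfg <- gait_sim_config(n_markers = 6, n_frames = 160, cycle_frames = 40,
                         n_harmonics = 3, latent_rank = 3, rng_seed = 50)
  sim <- generate_trajectories(cfg)
  X <- sim$truth$values
  expect_identical(sim$observed$values, X)  # noise_sd = 0

  d <- svd(X)$d
  expect_equal(sum(d > 1e-8 * d[1]), 3)

  # spectral support: DC, harmonics of the fundamental, and mirrors only
  Z <- unitary_dft(X)
  fund <- 160 / 40
  keep <- c(0, fund * (1:3), 160 - fund * (1:3))
  off_support <- setdiff(0:159, keep)
  peak <- max(Mod(Z))
  expect_lt(max(Mod(Z[off_support + 1, ])), 1e-10 * peak)

  # periodic: one cycle shift reproduces the signal
  expect_equal(X[1:40, ], X[41:80, ], tolerance = 1e-9)
})

test_that("a single shared latent factor makes all channels perfectly correlated", {
  cfg <- gait_sim_config(n_markers = 3, n_frames = 120, cycle_frames = 40,
                         n_harmonics = 2, latent_rank = 1, rng_seed = 51)
  X <- generate_trajectories(cfg)$truth$values
  cors <- abs(cor(X[, 1], X[, 2:9]))
  expect_true(all(cors > 1 - 1e-10))
})

test_that("generation and gap simulation are reproducible given a seed", {
  cfg <- gait_sim_config(n_markers = 4, n_frames = 80, cycle_frames = 20,
                         noise_sd = 2, rng_seed = 52)
  s1 <- generate_trajectories(cfg)
  s2 <- generate_trajectories(cfg)
  expect_identical(s1$observed$values, s2$observed$values)

  spec <- gap_spec(rng_seed = 53)
  g1 <- simulate_gaps(s1$truth, spec, 20)
  g2 <- simulate_gaps(s1$truth, spec, 20)
  expect_identical(g1$mask$observed, g2$mask$observed)
  expect_identical(g1$gaps, g2$gaps)
})

test_that("gap draws respect the configured count and length protocol", {
  cfg <- gait_sim_config(n_markers = 10, n_frames = 600, cycle_frames = 60,
                         rng_seed = 54)
  truth <- generate_trajectories(cfg)$truth
  for (seed in 1:10) {
    gp <- simulate_gaps(truth, gap_spec(rng_seed = seed), 60)
    draws <- attr(gp$gaps, "draws")
    expect_gte(nrow(draws), 5)
    expect_lte(nrow(draws), 20)
    expect_true(all(draws$length >= 0.10 * 60 & draws$length <= 0.50 * 60))
    # observed entries are untouched copies of the truth
    obs <- gp$mask$observed
    expect_identical(gp$gapped$values[obs], truth$values[obs])
    expect_true(all(is.na(gp$gapped$values[!obs])))
  }
})

test_that("gaps are marker-atomic: x, y, z always missing together", {
  cfg <- gait_sim_config(n_markers = 5, n_frames = 200, cycle_frames = 50,
                         rng_seed = 55)
  truth <- generate_trajectories(cfg)$truth
  gp <- simulate_gaps(truth, gap_spec(rng_seed = 56), 50)
  obs <- gp$mask$observed
  for (k in 1:5) {
    ch <- marker_channels(k)
    expect_true(all(rowSums(obs[, ch]) %in% c(0L, 3L)))
  }
})

test_that("the merged manifest matches the mask", {
  cfg <- gait_sim_config(n_markers = 3, n_frames = 100, cycle_frames = 20,
                         rng_seed = 57)
  truth <- generate_trajectories(cfg)$truth
  gp <- simulate_gaps(truth, gap_spec(c(8, 12), rng_seed = 58), 20)
  rebuilt <- matrix(TRUE, 100, 9)
  for (i in seq_len(nrow(gp$gaps))) {
    k <- match(gp$gaps$marker[i], truth$marker_names)
    rows <- (gp$gaps$start_frame[i] + 1):gp$gaps$end_frame[i]
    rebuilt[rows, marker_channels(k)] <- FALSE
  }
  expect_identical(rebuilt, gp$mask$observed)
})

test_that("an impossible gap length is rejected", {
  cfg <- gait_sim_config(n_markers = 2, n_frames = 40, cycle_frames = 20,
                         rng_seed = 59)
  truth <- generate_trajectories(cfg)$truth
  expect_error(simulate_gaps(truth, gap_spec(), 100), "cycle_frames")
})
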