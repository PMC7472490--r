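make_state <- function(n, m, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  admm_state(X = X, Q = matrix(rnorm(n * m), n, m),
             R = unitary_dft(matrix(rnorm(n * m), n, m)),
             A = matrix(rnorm(n * m), n, m),
             B = unitary_dft(matrix(rnorm(n * m), n, m)) * 0.1)
}

test_that("update_x is the exact constrained least-squares minimizer", {
  cfg <- solver_config(lambda = 1, mu_a = 0.7, mu_b = 1.3)
  n <- 3; m <- 3
  st <- make_state(n, m, seed = 10)
  set.seed(11)
  Yv <- matrix(rnorm(n * m), n, m)
  obs <- matrix(sample(c(TRUE, FALSE), n * m, replace = TRUE, prob = c(.6, .4)), n, m)
  Y <- trajectory_matrix(Yv, 100, "M1")
  mask <- observation_mask(obs)

  Xup <- update_x(st, Y, mask, cfg)
  expect_identical(Xup[obs], Yv[obs])

  M1 <- st$Q + st$A
  Z <- st$R + st$B
  Xor <- x_subproblem_oracle(M1, Z, Yv, obs, cfg$mu_a, cfg$mu_b)
  expect_lt(max(abs(Xup[!obs] - Xor[!obs])), 1e-5)

  # fully observed: projection dominates
  mask_all <- observation_mask(matrix(TRUE, n, m))
  expect_identical(update_x(st, Y, mask_all, cfg), Yv)

  # identical targets: weighted average of identical terms returns them
  M <- matrix(rnorm(n * m), n, m)
  st2 <- st; st2$Q <- M; st2$A <- matrix(0, n, m)
  st2$R <- unitary_dft(M); st2$B <- matrix(0i, n, m)
  X2 <- update_x(st2, Y, mask, cfg)
  expect_equal(X2[!obs], M[!obs], tolerance = 1e-12)
})

test_that("update_q solves the nuclear-norm prox of X - A", {
  cfg <- solver_config(mu_a = 0.5, mu_b = 1)
  st <- make_state(4, 4, seed = 12)
  expect_equal(update_q(st, cfg), svt(st$X - st$A, 2), tolerance = 1e-12)
  st$A <- st$X
  expect_equal(update_q(st, cfg), matrix(0, 4, 4), tolerance = 1e-12)
  # against the generic oracle
  set.seed(13)
  for (i in 1:3) {
    st <- make_state(4, 4, seed = 13 + i)
    expect_lt(max(abs(update_q(st, cfg) -
                        prox_nuclear_oracle(st$X - st$A, 1 / cfg$mu_a))), 1e-4)
  }
})

test_that("update_r applies the correct shrinkage in both modes", {
  n <- 6; m <- 4
  w <- spectral_weights(n, threshold_bin = 1, high_weight = 3, low_weight = 1)
  st <- make_state(n, m, seed = 20)
  C <- unitary_dft(st$X) - st$B

  cfg_e <- solver_config(lambda = 0.4, mu_b = 1.1, sparsity_mode = "entrywise")
  thr <- cfg_e$lambda * w$weights / cfg_e$mu_b
  Re_up <- update_r(st, w, cfg_e)
  expect_equal(Re_up, soft_threshold(C, matrix(thr, n, m)), tolerance = 1e-12)
  expect_lt(max(Mod(Re_up - prox_weighted_l1_oracle(C, thr))), 1e-4)

  cfg_g <- solver_config(lambda = 0.9, mu_b = 1.1, sparsity_mode = "group")
  thr_g <- cfg_g$lambda * w$weights / cfg_g$mu_b
  Rg <- update_r(st, w, cfg_g)
  expect_lt(max(Mod(Rg - prox_group_oracle(C, thr_g))), 1e-4)
  # group support: each row entirely zero or entirely scaled
  row_norms <- sqrt(rowSums(Mod(Rg)^2))
  for (i in seq_len(n)) {
    if (row_norms[i] == 0) {
      expect_true(all(Mod(Rg[i, ]) == 0))
    } else {
      ratio <- Rg[i, ] / C[i, ]
      expect_lt(max(Mod(ratio - ratio[1])), 1e-10)
    }
  }
})

test_that("multiplier updates accumulate the primal residuals", {
  st <- make_state(5, 3, seed = 30)
  # zero residual leaves multipliers unchanged
  st$Q <- st$X
  st$R <- unitary_dft(st$X)
  st2 <- update_multipliers(st)
  expect_equal(st2$A, st$A, tolerance = 1e-14)
  expect_equal(st2$B, st$B, tolerance = 1e-12)

  # constant residual accumulates additively
  st$A <- matrix(0, 5, 3)
  D <- matrix(1:15, 5, 3)
  st$Q <- st$X + D
  once <- update_multipliers(st)
  expect_equal(once$A, D)
  twice <- update_multipliers(once)
  expect_equal(twice$A, 2 * D)
})
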