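# Independent numerical minimizers for the proximal subproblems and the full
# convex objective. Each minimizes a slightly smoothed version of the
# nonsmooth objective (|z| -> sqrt(|z|^2 + eps^2)) by BFGS with analytic
# gradients; with eps = 1e-9 the smoothing bias is far below the tolerances
# asserted against them. These never call the closed-form prox operators they
# are used to check.

# argmin_Q ||Q||_* + 1/(2 gamma) ||Q - M||_F^2
prox_nuclear_oracle <- function(M, gamma, eps = 1e-9) {
  d <- dim(M)
  fn <- function(p) {
    Q <- matrix(p, d[1], d[2])
    s <- svd(Q)$d
    sum(sqrt(s^2 + eps^2)) + sum((Q - M)^2) / (2 * gamma)
  }
  gr <- function(p) {
    Q <- matrix(p, d[1], d[2])
    s <- svd(Q)
    G <- s$u %*% ((s$d / sqrt(s$d^2 + eps^2)) * t(s$v)) + (Q - M) / gamma
    as.vector(G)
  }
  o <- stats::optim(as.vector(M), fn, gr, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  matrix(o$par, d[1], d[2])
}

# argmin_R sum_ij thr_i |r_ij| + 1/2 ||R - C||_F^2 over complex R
prox_weighted_l1_oracle <- function(C, thr, eps = 1e-9) {
  d <- dim(C)
  np <- d[1] * d[2]
  Tm <- matrix(thr, d[1], d[2])
  fn <- function(p) {
    u <- matrix(p[1:np], d[1]); v <- matrix(p[-(1:np)], d[1])
    sum(Tm * sqrt(u^2 + v^2 + eps^2)) +
      0.5 * sum((u - Re(C))^2 + (v - Im(C))^2)
  }
  gr <- function(p) {
    u <- matrix(p[1:np], d[1]); v <- matrix(p[-(1:np)], d[1])
    mg <- sqrt(u^2 + v^2 + eps^2)
    c(as.vector(Tm * u / mg + (u - Re(C))),
      as.vector(Tm * v / mg + (v - Im(C))))
  }
  o <- stats::optim(c(as.vector(Re(C)), as.vector(Im(C))), fn, gr,
                    method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  matrix(o$par[1:np], d[1]) + 1i * matrix(o$par[-(1:np)], d[1])
}

# argmin_R sum_i thr_i ||r_i||_2 + 1/2 ||R - C||_F^2 over complex R
prox_group_oracle <- function(C, thr, eps = 1e-9) {
  d <- dim(C)
  np <- d[1] * d[2]
  fn <- function(p) {
    u <- matrix(p[1:np], d[1]); v <- matrix(p[-(1:np)], d[1])
    rn <- sqrt(rowSums(u^2 + v^2) + eps^2)
    sum(thr * rn) + 0.5 * sum((u - Re(C))^2 + (v - Im(C))^2)
  }
  gr <- function(p) {
    u <- matrix(p[1:np], d[1]); v <- matrix(p[-(1:np)], d[1])
    rn <- sqrt(rowSums(u^2 + v^2) + eps^2)
    c(as.vector(thr * u / rn + (u - Re(C))),
      as.vector(thr * v / rn + (v - Im(C))))
  }
  o <- stats::optim(c(as.vector(Re(C)), as.vector(Im(C))), fn, gr,
                    method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  matrix(o$par[1:np], d[1]) + 1i * matrix(o$par[-(1:np)], d[1])
}

# Constrained least squares of the X-subproblem:
# argmin_X mu_a/2 ||X - M1||^2 + mu_b/2 ||FX - Z||^2 s.t. observed entries = Y
x_subproblem_oracle <- function(M1, Z, Yv, obs, mu_a, mu_b) {
  free <- which(!obs)
  X0 <- Yv
  X0[free] <- 0
  fn <- function(p) {
    X <- X0; X[free] <- p
    mu_a / 2 * sum((X - M1)^2) + mu_b / 2 * sum(Mod(unitary_dft(X) - Z)^2)
  }
  o <- stats::optim(M1[free], fn, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  X0[free] <- o$par
  X0
}

# Minimum of the full S-LR objective over the free entries (smoothed BFGS),
# returning the true (unsmoothed) objective at the oracle minimizer.
slr_objective_oracle <- function(Yv, obs, weights, lambda, eps = 1e-8) {
  free <- which(!obs)
  X0 <- gaitfill:::interp_init(Yv, obs)
  X0[obs] <- Yv[obs]
  w <- weights$weights
  fn <- function(p) {
    X <- X0; X[free] <- p
    s <- svd(X)$d
    Z <- unitary_dft(X)
    sum(sqrt(s^2 + eps^2)) + lambda * sum(w * rowSums(sqrt(Mod(Z)^2 + eps^2)))
  }
  gr <- function(p) {
    X <- X0; X[free] <- p
    s <- svd(X)
    Z <- unitary_dft(X)
    Gnuc <- s$u %*% ((s$d / sqrt(s$d^2 + eps^2)) * t(s$v))
    Gl1 <- lambda * w * Z / sqrt(Mod(Z)^2 + eps^2)
    (Gnuc + Re(unitary_idft(Gl1)))[free]
  }
  o <- stats::optim(X0[free], fn, gr, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  X <- X0; X[free] <- o$par
  cfg <- solver_config(lambda = lambda, sparsity_mode = "entrywise")
  gaitfill:::recovery_objective(X, weights, cfg)
}
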