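#' Solver configuration for S-LR / GS-LR recovery
#'
#' @param lambda Non-negative trade-off between the nuclear-norm (low-rank)
#'   term and the spectral sparsity term. Scale-dependent: on millimetre-scale
#'   gait data good values lie around `1e4`–`1e5`; use [lambda_sweep()] to
#'   calibrate on new data scales.
#' @param mu_a,mu_b Positive augmented-Lagrangian penalties for the `Q = X`
#'   and `R = FX` splitting constraints. The solution is insensitive to these;
#'   they mainly affect convergence speed. Default 1.
#' @param sparsity_mode `"entrywise"` (weighted l1 on the spectrum: S-LR) or
#'   `"group"` (weighted l1,2 across each frequency row: GS-LR).
#' @param max_iter Maximum ADMM iterations (default 500).
#' @param tol Convergence tolerance on both relative primal residuals
#'   (default 1e-6).
#' @param window_frames Optional window length: the sequence is split into
#'   non-overlapping windows of this many frames, each completed
#'   independently. `NULL` (default) processes the full sequence.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(lambda = 1e4, mu_a = 1, mu_b = 1,
                          sparsity_mode = c("entrywise", "group"),
                          max_iter = 500L, tol = 1e-6,
                          window_frames = NULL) {
  sparsity_mode <- match.arg(sparsity_mode)
  stopifnot(lambda >= 0, mu_a > 0, mu_b > 0, max_iter >= 1, tol > 0)
  if (!is.null(window_frames)) stopifnot(window_frames >= 2)
  structure(
    list(lambda = lambda, mu_a = mu_a, mu_b = mu_b,
         sparsity_mode = sparsity_mode, max_iter = as.integer(max_iter),
         tol = tol, window_frames = window_frames),
    class = "solver_config"
  )
}

#' ADMM state for the split recovery problem
#'
#' Holds the primal estimate `X`, the auxiliary variables `Q` (low-rank copy,
#' real) and `R` (spectral copy, complex), and the scaled multipliers `A`
#' (for `Q = X`) and `B` (for `R = FX`). All five share the trajectory
#' matrix's shape.
#'
#' @param X,Q Real matrices.
#' @param R Complex (or real) matrix.
#' @param A Real multiplier matrix.
#' @param B Complex (or real) multiplier matrix.
#' @return Object of class `admm_state`.
#' @export
admm_state <- function(X, Q, R, A, B) {
  d <- dim(X)
  for (m in list(Q, R, A, B)) {
    if (!identical(dim(m), d)) stop("all state matrices must share one shape", call. = FALSE)
  }
  if (is.complex(X) || is.complex(Q) || is.complex(A)) {
    stop("X, Q and A must be real", call. = FALSE)
  }
  structure(list(X = X, Q = Q, R = R, A = A, B = B), class = "admm_state")
}

#' X-update: constrained least squares
#'
#' Exact minimizer of
#' `mu_a/2 ||X - (Q + A)||_F^2 + mu_b/2 ||FX - (R + B)||_F^2` subject to the
#' observed entries being fixed at `Y`. Because the DFT is unitary the
#' unconstrained minimizer is the weighted average
#' `(mu_a (Q + A) + mu_b F^H (R + B)) / (mu_a + mu_b)`; the constraint then
#' simply overwrites observed positions with `Y`.
#'
#' @param state An [admm_state()].
#' @param Y A [trajectory_matrix()] (observed data, values used at observed
#'   positions).
#' @param mask An [observation_mask()].
#' @param config A [solver_config()].
#' @return Real matrix, the updated `X`.
#' @export
update_x <- function(state, Y, mask, config) {
  if (config$mu_a + config$mu_b <= 0) {
    stop("mu_a + mu_b must be positive", call. = FALSE)
  }
  blend <- (config$mu_a * (state$Q + state$A) +
            config$mu_b * Re(unitary_idft(state$R + state$B))) /
           (config$mu_a + config$mu_b)
  obs <- mask$observed
  blend[obs] <- Y$values[obs]
  blend
}

#' Q-update: nuclear-norm proximal step
#'
#' Solves `argmin_Q ||Q||_* + mu_a/2 ||Q - (X - A)||_F^2`, i.e.
#' `svt(X - A, 1/mu_a)`.
#'
#' @inheritParams update_x
#' @return Real matrix, the updated `Q`.
#' @export
update_q <- function(state, config) {
  svt(state$X - state$A, 1 / config$mu_a)
}

#' R-update: spectral shrinkage
#'
#' Forms `C = F X - B` and applies, per frequency row `i` with weight `w_i`:
#' entrywise mode, complex soft-thresholding at `lambda * w_i / mu_b`
#' (S-LR); group mode, joint shrinkage of the whole row by
#' `max(||c_i|| - lambda * w_i / mu_b, 0) / ||c_i||` (GS-LR), so a frequency
#' is kept or discarded for all channels at once.
#'
#' @inheritParams update_x
#' @param weights A [spectral_weights()] whose length equals `nrow(X)`.
#' @return Complex matrix, the updated `R`.
#' @export
update_r <- function(state, weights, config) {
  C <- unitary_dft(state$X) - state$B
  thr <- config$lambda * weights$weights / config$mu_b
  if (config$sparsity_mode == "entrywise") {
    soft_threshold(C, matrix(thr, nrow(C), ncol(C)))
  } else {
    group_shrink_rows(C, thr)
  }
}

#' Multiplier update
#'
#' Standard scaled dual ascent: `A <- A + (Q - X)`,
#' `B <- B + (R - FX)`.
#'
#' @inheritParams update_x
#' @return The updated [admm_state()].
#' @export
update_multipliers <- function(state) {
  FX <- unitary_dft(state$X)
  state$A <- state$A + (state$Q - state$X)
  state$B <- state$B + (state$R - FX)
  state
}

# Objective of the original (unsplit) problem at X.
recovery_objective <- function(X, weights, config) {
  FX <- unitary_dft(X)
  pen <- if (config$sparsity_mode == "entrywise") {
    sum(weights$weights * rowSums(Mod(FX)))
  } else {
    sum(weights$weights * sqrt(rowSums(Mod(FX)^2)))
  }
  nuclear_norm(X) + config$lambda * pen
}

#' Recover missing marker trajectories by S-LR / GS-LR matrix completion
#'
#' Completes the missing entries of a marker trajectory matrix by minimizing
#' `||X||_* + lambda ||W F X||` (l1 or row-group l1,2 norm, per
#' `config$sparsity_mode`) subject to exact agreement with the observed
#' entries, via ADMM with closed-form proximal updates. Initialization is
#' deterministic: missing entries are linearly interpolated per channel
#' (constant extension at the ends), `Q = X`, `R = FX`, zero multipliers.
#' Iteration stops when both relative primal residuals
#' `||Q - X||_F / max(1, ||X||_F)` and `||R - FX||_F / max(1, ||FX||_F)`
#' drop below `config$tol`, or after `config$max_iter` sweeps (then a warning
#' is emitted and `converged = FALSE` is returned, never an error).
#'
#' @param Y A [trajectory_matrix()]; `NA`/`NaN` entries are the gaps when no
#'   mask is given.
#' @param mask Optional [observation_mask()]; defaults to
#'   [mask_from_values()] of `Y`.
#' @param weights Optional [spectral_weights()]; defaults to
#'   `spectral_weights(n_frames)` (cut-off at folded bin 100, weights 100/1).
#' @param config A [solver_config()].
#' @return Object of class `recovery_result`: `completed` (a
#'   [trajectory_matrix()] equal to `Y` at every observed entry), `iterations`,
#'   `converged`, `residual_history` (`iterations x 2` matrix of the two
#'   relative primal residuals), `objective_history`.
#' @examples
#' cfg <- gait_sim_config(n_markers = 4, n_frames = 120, cycle_frames = 40,
#'                        n_harmonics = 2, latent_rank = 3, rng_seed = 7)
#' sim <- generate_trajectories(cfg)
#' gp <- simulate_gaps(sim$truth, gap_spec(c(2, 4), rng_seed = 8), 40)
#' res <- recover_trajectories(gp$gapped, gp$mask,
#'                             weights = spectral_weights(120, 10),
#'                             config = solver_config(lambda = 10, max_iter = 200))
#' res$converged
#' @export
recover_trajectories <- function(Y, mask = NULL, weights = NULL,
                                 config = solver_config()) {
  stopifnot(inherits(Y, "trajectory_matrix"), inherits(config, "solver_config"))
  mask <- check_mask(Y, mask)
  check_recoverable(Y, mask)

  if (!is.null(config$window_frames)) {
    return(recover_windowed(Y, mask, weights, config))
  }

  n <- nrow(Y$values)
  if (is.null(weights)) weights <- spectral_weights(n)
  stopifnot(inherits(weights, "spectral_weights"))
  if (length(weights$weights) != n) {
    stop("spectral weights length must equal the number of frames", call. = FALSE)
  }

  obs <- mask$observed
  X <- interp_init(Y$values, obs)
  X[obs] <- Y$values[obs]
  state <- admm_state(X = X, Q = X, R = unitary_dft(X),
                      A = array(0, dim(X)), B = array(0i, dim(X)))

  res_hist <- matrix(NA_real_, config$max_iter, 2,
                     dimnames = list(NULL, c("primal_q", "primal_r")))
  obj_hist <- numeric(config$max_iter)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$max_iter)) {
    state$X <- update_x(state, Y, mask, config)
    state$Q <- update_q(state, config)
    state$R <- update_r(state, weights, config)
    FX <- unitary_dft(state$X)
    state$A <- state$A + (state$Q - state$X)
    state$B <- state$B + (state$R - FX)

    r_q <- fro(state$Q - state$X) / max(1, fro(state$X))
    r_r <- fro(state$R - FX) / max(1, fro(FX))
    res_hist[it, ] <- c(r_q, r_r)
    obj_hist[it] <- recovery_objective(state$X, weights, config)
    if (r_q < config$tol && r_r < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "ADMM did not reach tol = %g within %d iterations (residuals %.3g / %.3g)",
      config$tol, config$max_iter, res_hist[it, 1], res_hist[it, 2]
    ), call. = FALSE)
  }

  completed <- Y
  completed$values[] <- state$X
  completed$values[obs] <- Y$values[obs]
  structure(
    list(completed = completed, iterations = it, converged = converged,
         residual_history = res_hist[seq_len(it), , drop = FALSE],
         objective_history = obj_hist[seq_len(it)],
         config = config),
    class = "recovery_result"
  )
}

recover_windowed <- function(Y, mask, weights, config) {
  n <- nrow(Y$values)
  wf <- as.integer(config$window_frames)
  starts <- seq(1L, n, by = wf)
  sub_cfg <- config
  sub_cfg$window_frames <- NULL
  out <- Y$values
  iters <- 0L
  conv <- TRUE
  for (s in starts) {
    e <- min(s + wf - 1L, n)
    if (e - s + 1L < 2L) { # tail shorter than 2 frames joins the previous window
      s <- max(1L, e - 1L)
    }
    rows <- s:e
    sub_y <- trajectory_matrix(Y$values[rows, , drop = FALSE], Y$frame_rate,
                               Y$marker_names)
    sub_mask <- observation_mask(mask$observed[rows, , drop = FALSE])
    sub_w <- if (is.null(weights)) NULL else {
      spectral_weights(length(rows), weights$threshold_bin,
                       weights$high_weight, weights$low_weight)
    }
    r <- recover_trajectories(sub_y, sub_mask, sub_w, sub_cfg)
    out[rows, ] <- r$completed$values
    iters <- iters + r$iterations
    conv <- conv && r$converged
  }
  completed <- Y
  completed$values[] <- out
  structure(
    list(completed = completed, iterations = iters, converged = conv,
         residual_history = NULL, objective_history = NULL, config = config),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "<recovery_result> %d iterations, converged = %s\n",
    x$iterations, x$converged
  ))
  invisible(x)
}
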