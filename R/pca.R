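#' Configuration for the iterative-PCA imputation baseline
#'
#' Exactly one of `n_components` and `variance_threshold` selects the
#' subspace dimension; if neither is given, `variance_threshold = 0.95` is
#' used.
#'
#' @param n_components Fixed number of principal components, or `NULL`.
#' @param variance_threshold Fraction of variance in (0, 1] the retained
#'   components must explain, or `NULL`.
#' @param max_iter Maximum refinement sweeps (default 200).
#' @param tol Relative change in the imputed entries below which iteration
#'   stops (default 1e-6).
#' @return Object of class `pca_baseline_config`.
#' @export
pca_baseline_config <- function(n_components = NULL, variance_threshold = NULL,
                                max_iter = 200L, tol = 1e-6) {
  if (is.null(n_components) && is.null(variance_threshold)) {
    variance_threshold <- 0.95
  }
  if (!is.null(n_components) && !is.null(variance_threshold)) {
    stop("set exactly one of 'n_components' and 'variance_threshold'", call. = FALSE)
  }
  if (!is.null(n_components)) stopifnot(n_components >= 1L)
  if (!is.null(variance_threshold)) {
    stopifnot(variance_threshold > 0, variance_threshold <= 1)
  }
  stopifnot(max_iter >= 1L, tol > 0)
  structure(
    list(n_components = if (is.null(n_components)) NULL else as.integer(n_components),
         variance_threshold = variance_threshold,
         max_iter = as.integer(max_iter), tol = tol),
    class = "pca_baseline_config"
  )
}

#' Fill gaps by iterative PCA imputation
#'
#' Conventional EM-style PCA completion, used as the comparison baseline for
#' the convex solvers: initialize missing entries by per-channel linear
#' interpolation, then repeat \{center the channels, compute the leading
#' principal subspace of the current completed matrix, re-project onto it,
#' restore the observed entries\} until the relative change in the imputed
#' entries falls below `config$tol` or `config$max_iter` is reached.
#' Deterministic: component signs are fixed by making each component's
#' largest-magnitude loading positive.
#'
#' @param Y A [trajectory_matrix()] with `NA` gaps.
#' @param mask Optional [observation_mask()]; defaults to
#'   [mask_from_values()].
#' @param config A [pca_baseline_config()].
#' @return A `recovery_result` (see [recover_trajectories()]);
#'   `residual_history` holds the per-sweep relative change in imputed
#'   entries.
#' @export
pca_impute <- function(Y, mask = NULL, config = pca_baseline_config()) {
  stopifnot(inherits(Y, "trajectory_matrix"),
            inherits(config, "pca_baseline_config"))
  mask <- check_mask(Y, mask)
  check_recoverable(Y, mask)
  obs <- mask$observed
  V <- Y$values

  X <- interp_init(V, obs)
  X[obs] <- V[obs]
  miss <- !obs
  if (!any(miss)) {
    completed <- Y
    return(structure(
      list(completed = completed, iterations = 0L, converged = TRUE,
           residual_history = numeric(0), objective_history = NULL,
           config = config),
      class = "recovery_result"
    ))
  }

  changes <- numeric(config$max_iter)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$max_iter)) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    s <- robust_svd(Xc)
    k <- if (!is.null(config$n_components)) {
      min(config$n_components, length(s$d))
    } else {
      var_expl <- cumsum(s$d^2) / sum(s$d^2)
      which(var_expl >= config$variance_threshold)[1]
    }
    # deterministic sign: largest-|loading| entry of each component positive
    for (j in seq_len(k)) {
      i_max <- which.max(abs(s$v[, j]))
      if (s$v[i_max, j] < 0) {
        s$v[, j] <- -s$v[, j]
        s$u[, j] <- -s$u[, j]
      }
    }
    Xhat <- s$u[, seq_len(k), drop = FALSE] %*%
      (s$d[seq_len(k)] * t(s$v[, seq_len(k), drop = FALSE]))
    Xhat <- sweep(Xhat, 2L, mu, `+`)

    old_miss <- X[miss]
    X[miss] <- Xhat[miss]
    X[obs] <- V[obs]
    changes[it] <- fro(X[miss] - old_miss) / max(1, fro(old_miss))
    if (changes[it] < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "PCA imputation did not reach tol = %g within %d sweeps",
      config$tol, config$max_iter
    ), call. = FALSE)
  }

  completed <- Y
  completed$values[] <- X
  completed$values[obs] <- V[obs]
  structure(
    list(completed = completed, iterations = it, converged = converged,
         residual_history = changes[seq_len(it)], objective_history = NULL,
         config = config),
    class = "recovery_result"
  )
}
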