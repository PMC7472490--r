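#' Per-gap 3D reconstruction error
#'
#' For every marker-frame that was missing, the error is the Euclidean
#' distance (mm) between the recovered and the true 3D marker position,
#' `|d_rec - d_full|`. Observed positions contribute nothing (recovery keeps
#' them fixed).
#'
#' @param recovered,truth [trajectory_matrix()] objects of equal shape.
#' @param mask The [observation_mask()] of the gapped input that was
#'   recovered.
#' @param method,setting Optional labels carried into the report.
#' @return Object of class `error_report`: `per_entry` (data frame with
#'   `marker`, `frame` (0-based), `error_mm`), `mean_error`, `median_error`,
#'   `method`, `setting`, and (when produced by [run_experiment()])
#'   `per_repetition_means`. If nothing was missing an empty report is
#'   returned with a warning.
#' @examples
#' # a 3-4-5 offset on one missing marker-frame gives a 5 mm error
#' @export
reconstruction_error <- function(recovered, truth, mask,
                                 method = NULL, setting = NULL) {
  stopifnot(inherits(recovered, "trajectory_matrix"),
            inherits(truth, "trajectory_matrix"),
            inherits(mask, "observation_mask"))
  if (!identical(dim(recovered$values), dim(truth$values)) ||
      !identical(dim(mask$observed), dim(truth$values))) {
    stop("recovered, truth and mask must share one shape", call. = FALSE)
  }
  m <- length(truth$marker_names)
  rows <- list()
  for (k in seq_len(m)) {
    ch <- marker_channels(k)
    missing_frames <- which(!mask$observed[, ch[1]] |
                            !mask$observed[, ch[2]] |
                            !mask$observed[, ch[3]])
    if (length(missing_frames) == 0L) next
    diff <- recovered$values[missing_frames, ch, drop = FALSE] -
      truth$values[missing_frames, ch, drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      marker = truth$marker_names[k],
      frame = missing_frames - 1L,
      error_mm = sqrt(rowSums(diff^2))
    )
  }
  if (length(rows) == 0L) {
    warning("no missing entries; empty error report", call. = FALSE)
    per_entry <- data.frame(marker = character(), frame = integer(),
                            error_mm = numeric())
    return(structure(
      list(per_entry = per_entry, mean_error = NaN, median_error = NaN,
           method = method, setting = setting, per_repetition_means = NULL),
      class = "error_report"
    ))
  }
  per_entry <- do.call(rbind, rows)
  structure(
    list(per_entry = per_entry,
         mean_error = mean(per_entry$error_mm),
         median_error = stats::median(per_entry$error_mm),
         method = method, setting = setting, per_repetition_means = NULL),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report>%s%s %d gap samples, mean %.3f mm, median %.3f mm\n",
    if (is.null(x$method)) "" else paste0(" ", x$method, ":"),
    if (is.null(x$setting)) "" else paste0(" [", x$setting, "]"),
    nrow(x$per_entry), x$mean_error, x$median_error
  ))
  invisible(x)
}

solver_for_method <- function(method, gapped, mask, weights, solver_cfg,
                              pca_cfg) {
  switch(method,
    "s-lr" = {
      cfg <- solver_cfg
      cfg$sparsity_mode <- "entrywise"
      recover_trajectories(gapped, mask, weights, cfg)
    },
    "gs-lr" = {
      cfg <- solver_cfg
      cfg$sparsity_mode <- "group"
      recover_trajectories(gapped, mask, weights, cfg)
    },
    "pca" = pca_impute(gapped, mask, pca_cfg),
    stop(sprintf("unknown method '%s' (use s-lr, gs-lr or pca)", method),
         call. = FALSE)
  )
}

#' Repeated synthetic gap-filling experiment
#'
#' For each repetition: generate a fresh synthetic capture, optionally
#' restrict it to a marker subset (emulating a sparse one-marker-per-limb
#' setting), punch a fresh set of gaps, run every method on the identical
#' gapped input, and score against the noiseless truth with
#' [reconstruction_error()]. Seeds for each repetition are derived
#' deterministically from `master_seed` and the repetition index, so the
#' whole experiment is reproducible and every method sees the same inputs.
#'
#' @param sim_cfg A [gait_sim_config()].
#' @param spec A [gap_spec()]; `spec$repetitions` repetitions are run.
#' @param methods Character subset of `c("s-lr", "gs-lr", "pca")`.
#' @param marker_subset Optional character vector of marker names to keep
#'   before gaps are punched.
#' @param weights Optional [spectral_weights()] for the convex solvers.
#' @param solver_cfg A [solver_config()] shared by s-lr and gs-lr (the
#'   sparsity mode is overridden per method).
#' @param pca_cfg A [pca_baseline_config()].
#' @param master_seed Integer master seed (default `spec$rng_seed`).
#' @return Named list of `error_report`, one per method, each with
#'   `per_repetition_means` of length `spec$repetitions` and per-entry errors
#'   pooled over repetitions.
#' @export
run_experiment <- function(sim_cfg, spec,
                           methods = c("s-lr", "gs-lr", "pca"),
                           marker_subset = NULL, weights = NULL,
                           solver_cfg = solver_config(),
                           pca_cfg = pca_baseline_config(),
                           master_seed = spec$rng_seed) {
  stopifnot(inherits(sim_cfg, "gait_sim_config"), inherits(spec, "gap_spec"))
  methods <- unique(methods)
  for (mth in methods) {
    if (!mth %in% c("s-lr", "gs-lr", "pca")) {
      stop(sprintf("unknown method '%s'", mth), call. = FALSE)
    }
  }
  reps <- spec$repetitions
  per_rep <- matrix(NA_real_, reps, length(methods),
                    dimnames = list(NULL, methods))
  pooled <- stats::setNames(vector("list", length(methods)), methods)

  for (r in seq_len(reps)) {
    cfg_r <- sim_cfg
    cfg_r$rng_seed <- (master_seed + 2L * r) %% .Machine$integer.max
    sim <- generate_trajectories(cfg_r)
    truth <- sim$truth
    observed <- sim$observed
    if (!is.null(marker_subset)) {
      keep <- match(marker_subset, truth$marker_names)
      if (anyNA(keep)) stop("marker_subset contains unknown markers", call. = FALSE)
      ch <- as.vector(vapply(keep, marker_channels, integer(3)))
      truth <- trajectory_matrix(truth$values[, ch, drop = FALSE],
                                 truth$frame_rate, marker_subset)
      observed <- trajectory_matrix(observed$values[, ch, drop = FALSE],
                                    observed$frame_rate, marker_subset)
    }
    spec_r <- spec
    spec_r$rng_seed <- (master_seed + 2L * r + 1L) %% .Machine$integer.max
    gp <- simulate_gaps(observed, spec_r, sim_cfg$cycle_frames)

    for (mth in methods) {
      res <- suppressWarnings(
        solver_for_method(mth, gp$gapped, gp$mask, weights, solver_cfg, pca_cfg)
      )
      rep_report <- reconstruction_error(res$completed, truth, gp$mask)
      per_rep[r, mth] <- rep_report$mean_error
      rep_report$per_entry$repetition <- r
      pooled[[mth]] <- c(pooled[[mth]], list(rep_report$per_entry))
    }
  }

  setting <- sprintf("%d markers", length(truth$marker_names))
  out <- stats::setNames(vector("list", length(methods)), methods)
  for (mth in methods) {
    per_entry <- do.call(rbind, pooled[[mth]])
    out[[mth]] <- structure(
      list(per_entry = per_entry,
           mean_error = mean(per_entry$error_mm),
           median_error = stats::median(per_entry$error_mm),
           method = mth, setting = setting,
           per_repetition_means = unname(per_rep[, mth])),
      class = "error_report"
    )
  }
  out
}

#' Pairwise Wilcoxon signed-rank comparison of methods
#'
#' Pairs methods by repetition (each repetition used identical gapped
#' inputs) and applies the Wilcoxon signed-rank test to the per-repetition
#' mean errors. If two methods produced identical error vectors the test is
#' degenerate; `p = 1` is reported with a warning.
#'
#' @param reports List of `error_report` objects from [run_experiment()]
#'   (at least two, equal repetition counts).
#' @param alternative Passed to [stats::wilcox.test()]; `"two.sided"`
#'   (default), `"less"` (first method's errors smaller) or `"greater"`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Data frame with one row per method pair: `method_a`, `method_b`,
#'   `p_value`, `significant`.
#' @export
compare_methods <- function(reports, alternative = "two.sided", alpha = 0.05) {
  if (length(reports) < 2L) stop("need at least two method reports", call. = FALSE)
  means <- lapply(reports, function(r) {
    if (is.null(r$per_repetition_means)) {
      stop("reports must carry per-repetition means (use run_experiment)",
           call. = FALSE)
    }
    r$per_repetition_means
  })
  lens <- lengths(means)
  if (length(unique(lens)) != 1L) {
    stop("all methods must have the same number of repetitions", call. = FALSE)
  }
  labels <- vapply(seq_along(reports), function(i) {
    if (!is.null(reports[[i]]$method)) reports[[i]]$method else paste0("method", i)
  }, character(1))

  pairs <- utils::combn(length(reports), 2L)
  out <- data.frame(method_a = character(), method_b = character(),
                    p_value = numeric(), significant = logical())
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- means[[i]] - means[[j]]
    if (all(d == 0)) {
      warning(sprintf("all paired differences are zero for %s vs %s; p set to 1",
                      labels[i], labels[j]), call. = FALSE)
      pv <- 1
    } else {
      pv <- suppressWarnings(
        stats::wilcox.test(means[[i]], means[[j]], paired = TRUE,
                           alternative = alternative)$p.value
      )
    }
    out <- rbind(out, data.frame(method_a = labels[i], method_b = labels[j],
                                 p_value = pv, significant = pv < alpha))
  }
  attr(out, "test") <- "Wilcoxon signed-rank (paired, per-repetition means)"
  attr(out, "alpha") <- alpha
  out
}

#' Reconstruction error as a function of the sparsity weight lambda
#'
#' Re-solves the same gapped instance at each lambda and reports the mean
#' reconstruction error, tracing the trade-off between the pure low-rank
#' solution (`lambda = 0`) and a fully thresholded spectrum (very large
#' lambda).
#'
#' @param truth Ground-truth [trajectory_matrix()].
#' @param gapped The gapped input [trajectory_matrix()].
#' @param mask The gapped input's [observation_mask()].
#' @param lambdas Non-negative, sorted values to try (non-empty).
#' @param sparsity_mode `"entrywise"` (S-LR) or `"group"` (GS-LR).
#' @param weights Optional [spectral_weights()].
#' @param config Base [solver_config()]; its `lambda` and `sparsity_mode`
#'   are overridden.
#' @return Data frame `(lambda, mean_error)`, with the best lambda in
#'   `attr(, "best_lambda")`.
#' @export
lambda_sweep <- function(truth, gapped, mask, lambdas,
                         sparsity_mode = c("entrywise", "group"),
                         weights = NULL, config = solver_config()) {
  sparsity_mode <- match.arg(sparsity_mode)
  if (length(lambdas) == 0L) stop("'lambdas' must be non-empty", call. = FALSE)
  if (any(lambdas < 0) || is.unsorted(lambdas)) {
    stop("'lambdas' must be non-negative and sorted", call. = FALSE)
  }
  errs <- vapply(lambdas, function(l) {
    cfg <- config
    cfg$lambda <- l
    cfg$sparsity_mode <- sparsity_mode
    res <- suppressWarnings(recover_trajectories(gapped, mask, weights, cfg))
    reconstruction_error(res$completed, truth, mask)$mean_error
  }, numeric(1))
  out <- data.frame(lambda = lambdas, mean_error = errs)
  attr(out, "best_lambda") <- lambdas[which.min(errs)]
  out
}
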