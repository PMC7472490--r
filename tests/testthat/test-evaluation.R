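tiny_pair <- function() {
  vals <- matrix(seq_len(60) * 1.0, 10, 6)
  truth <- trajectory_matrix(vals, 100, c("A", "B"))
  obs <- matrix(TRUE, 10, 6)
  obs[3, 1:3] <- FALSE
  list(truth = truth, mask = observation_mask(obs))
}

test_that("reconstruction error is the 3D distance at missing marker-frames", {
  tp <- tiny_pair()
  rec <- tp$truth
  expect_equal(reconstruction_error(rec, tp$truth, tp$mask)$mean_error, 0)

  rec$values[3, 1:3] <- rec$values[3, 1:3] + c(3, 4, 0)
  rep1 <- reconstruction_error(rec, tp$truth, tp$mask)
  expect_equal(rep1$per_entry$error_mm, 5)
  expect_equal(rep1$per_entry$frame, 2L)  # 0-based
  expect_equal(rep1$per_entry$marker, "A")

  # hand-computed average over several offsets
  obs <- matrix(TRUE, 10, 6)
  obs[c(2, 5, 8), 4:6] <- FALSE
  mask <- observation_mask(obs)
  rec2 <- tp$truth
  offsets <- rbind(c(1, 0, 0), c(0, 2, 0), c(2, 3, 6))
  rec2$values[c(2, 5, 8), 4:6] <- rec2$values[c(2, 5, 8), 4:6] + offsets
  rep2 <- reconstruction_error(rec2, tp$truth, mask)
  expect_equal(rep2$mean_error, mean(c(1, 2, 7)), tolerance = 1e-12)
  expect_equal(rep2$median_error, 2)
})

test_that("observed entries contribute nothing to the error report", {
  tp <- tiny_pair()
  rec <- tp$truth
  rec$values[tp$mask$observed] <- rec$values[tp$mask$observed] + 100
  rec$values[3, 1:3] <- tp$truth$values[3, 1:3]
  expect_equal(reconstruction_error(rec, tp$truth, tp$mask)$mean_error, 0)
})

test_that("an all-observed mask yields an empty report with a warning", {
  tp <- tiny_pair()
  mask <- observation_mask(matrix(TRUE, 10, 6))
  expect_warning(rep0 <- reconstruction_error(tp$truth, tp$truth, mask),
                 "no missing")
  expect_equal(nrow(rep0$per_entry), 0)
})

test_that("the experiment is deterministic and shaped by the protocol", {
  sim_cfg <- gait_sim_config(n_markers = 6, n_frames = 160, cycle_frames = 40,
                             rng_seed = 70)
  spec <- gap_spec(repetitions = 3, rng_seed = 71)
  scfg <- solver_config(lambda = 100, max_iter = 60, tol = 1e-4)
  out1 <- run_experiment(sim_cfg, spec, methods = c("gs-lr", "pca"),
                         weights = spectral_weights(160, 10), solver_cfg = scfg)
  out2 <- run_experiment(sim_cfg, spec, methods = c("gs-lr", "pca"),
                         weights = spectral_weights(160, 10), solver_cfg = scfg)
  expect_identical(out1[["gs-lr"]]$per_repetition_means,
                   out2[["gs-lr"]]$per_repetition_means)
  expect_length(out1[["pca"]]$per_repetition_means, 3)
  expect_identical(out1[["pca"]]$per_entry, out2[["pca"]]$per_entry)
  # identical gapped inputs per method: both methods scored the same gaps
  expect_identical(out1[["gs-lr"]]$per_entry[c("marker", "frame", "repetition")],
                   out1[["pca"]]$per_entry[c("marker", "frame", "repetition")])
  expect_error(run_experiment(sim_cfg, spec, methods = "spline"), "unknown method")
})

test_that("a marker subset restricts the channels seen by the solvers", {
  sim_cfg <- gait_sim_config(n_markers = 6, n_frames = 80, cycle_frames = 20,
                             rng_seed = 72)
  spec <- gap_spec(c(2, 4), repetitions = 1, rng_seed = 73)
  out <- run_experiment(sim_cfg, spec, methods = "pca",
                        marker_subset = c("M01", "M03"))
  expect_match(out[["pca"]]$setting, "2 markers")
  expect_true(all(out[["pca"]]$per_entry$marker %in% c("M01", "M03")))
  expect_error(
    run_experiment(sim_cfg, spec, methods = "pca", marker_subset = "nope"),
    "unknown markers"
  )
})

test_that("Wilcoxon comparison flags one-sided shifts and degenerate ties", {
  mk <- function(label, x) {
    structure(list(method = label, per_repetition_means = x),
              class = "error_report")
  }
  b <- seq(1, 20) / 3
  # constant +5 mm shift: all signed ranks on one side
  res <- compare_methods(list(mk("worse", b + 5), mk("better", b)))
  expect_lt(res$p_value, 0.001)
  expect_true(res$significant)

  # antisymmetric differences: no evidence of a shift
  d <- rep(c(2, -2), 10) + rep(c(0.001, -0.001), each = 10)
  res2 <- compare_methods(list(mk("a", b + d), mk("b", b)))
  expect_gt(res2$p_value, 0.5)

  # identical vectors degenerate to p = 1 with a warning
  expect_warning(res3 <- compare_methods(list(mk("a", b), mk("b", b))),
                 "zero")
  expect_equal(res3$p_value, 1)

  expect_error(compare_methods(list(mk("a", b))), "at least two")
  expect_error(compare_methods(list(mk("a", b), mk("b", b[1:10]))),
               "same number")
})

test_that("lambda sweep traces the error curve and reports the argmin", {
  inst <- standard_instance()
  cfg <- solver_config(max_iter = 200, tol = 1e-6)
  sweep <- suppressWarnings(lambda_sweep(
    inst$truth, inst$gapped, inst$mask, c(0, 10, 1e12),
    sparsity_mode = "entrywise", weights = inst$weights, config = cfg
  ))
  expect_equal(sweep$lambda, c(0, 10, 1e12))
  expect_true(all(is.finite(sweep$mean_error)))
  expect_equal(attr(sweep, "best_lambda"),
               sweep$lambda[which.min(sweep$mean_error)])
  expect_error(lambda_sweep(inst$truth, inst$gapped, inst$mask, numeric(0)),
               "non-empty")
  expect_error(lambda_sweep(inst$truth, inst$gapped, inst$mask, c(10, 1)),
               "sorted")
})
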