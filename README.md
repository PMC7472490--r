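# gaitfill

Gap filling for optical motion-capture marker trajectories by convex
low-rank + spectral-sparsity matrix completion.

## The problem

Marker-based motion capture loses data whenever a marker is occluded or
detaches: the output contains gaps where a marker's 3D position is missing
for a contiguous stretch of frames. Spline interpolation fails on long gaps,
and kinematic or learned methods need skeleton models or training data.
`gaitfill` is for movement scientists, biomechanists and animators who want
an *unsupervised* post-processing step that reconstructs gaps using only the
structure of the capture itself.

## The models

Store the capture as $X \in \mathbb{R}^{n \times 3m}$ ($n$ frames, $m$
markers, three coordinate channels per marker), with observed entries
$\Omega$ of the measured matrix $Y$, and let $F$ be the unitary DFT applied
to each channel. Gait trajectories are (1) highly correlated across markers,
(2) periodic and low-frequency, and (3) supported on the *same* frequency
bins in every channel. Two convex estimators encode this:

- **S-LR** (sparse low-rank):
  $\min_X \|X\|_* + \lambda\,\|W F X\|_1$ s.t. $P_\Omega(X)=P_\Omega(Y)$
- **GS-LR** (group-sparse low-rank):
  $\min_X \|X\|_* + \lambda\,\|W F X\|_{1,2}$ s.t. $P_\Omega(X)=P_\Omega(Y)$

$\|X\|_*$ (nuclear norm) is the convex surrogate for rank; $W$ weights
frequency bins (heavy above a cut-off $\theta_f$, default weights 100/1);
the row-group norm $\|M\|_{1,2}=\sum_i \|m_i\|_2$ makes GS-LR keep or kill
each frequency jointly across all channels. Both are solved by ADMM with
closed-form proximal steps: singular-value thresholding for the nuclear
norm, complex soft-thresholding (S-LR) or row-group shrinkage (GS-LR) for
the spectrum, and an exact constrained least-squares update that pins
observed entries to $Y$ bit-exactly. An iterative-PCA imputation baseline,
a synthetic gait generator, a seeded gap-simulation protocol and a Wilcoxon
comparison harness round out the toolkit. See
`vignettes/gap-filling-methods.Rmd` for the full methodology.

## Worked example

```r
library(gaitfill)

# a synthetic capture: 6 markers, 240 Hz, 5 gait cycles of 60 frames
cfg <- gait_sim_config(n_markers = 6, n_frames = 300, frame_rate = 240,
                       cycle_frames = 60, rng_seed = 42)
sim <- generate_trajectories(cfg)

# punch 5-20 random gaps of 10-50% of a cycle (all 3 coordinates go missing)
gp <- simulate_gaps(sim$truth, gap_spec(rng_seed = 43), cycle_frames = 60)
print(gp$gapped)
#> <trajectory_matrix> 300 frames x 6 markers (18 channels) @ 240 Hz, 810 missing entries
head(gp$gaps, 3)
#>   marker start_frame end_frame
#> 1    M01         229       251
#> 2    M01         262       282
#> 3    M02          80       110

# group-sparse low-rank recovery
res <- recover_trajectories(gp$gapped, gp$mask,
                            weights = spectral_weights(300, threshold_bin = 20),
                            config = solver_config(lambda = 1e4,
                                                   sparsity_mode = "group",
                                                   tol = 1e-5))
print(res)
#> <recovery_result> 111 iterations, converged = TRUE

reconstruction_error(res$completed, sim$truth, gp$mask, method = "gs-lr")
#> <error_report> gs-lr: 270 gap samples, mean 0.006 mm, median 0.004 mm

# the PCA baseline on the identical input
base <- pca_impute(gp$gapped, gp$mask)
reconstruction_error(base$completed, sim$truth, gp$mask, method = "pca")
#> <error_report> pca: 270 gap samples, mean 4.028 mm, median 2.878 mm
```

270 marker-frames were missing; GS-LR reconstructs them to ~0.006 mm mean
error on this noiseless low-rank instance, versus ~4 mm for iterative PCA —
gaps up to half a gait cycle are recovered essentially exactly because the
solver pools frequency support across all channels. Errors are Euclidean
distances between the recovered and true 3D positions, in millimetres,
evaluated only at originally-missing marker-frames.

A command-line wrapper over the same functions ships at
`inst/cli/gaitfill.R`:

```sh
Rscript inst/cli/gaitfill.R simulate --config sim.yaml --out truth.csv --gaps gaps.csv
Rscript inst/cli/gaitfill.R recover  --input truth_gapped.csv --method gs-lr \
        --lambda 1e4 --out completed.csv
Rscript inst/cli/gaitfill.R evaluate --truth truth.csv --methods s-lr,gs-lr,pca \
        --reps 20 --out report.json
Rscript inst/cli/gaitfill.R sweep-lambda --truth truth.csv --gapped truth_gapped.csv \
        --lambdas 1e2,1e3,1e4,1e5 --out sweep.csv
```

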