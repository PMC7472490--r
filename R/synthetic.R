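# Deterministic scoped RNG: run code under a seed, restore the caller's
# random state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Configuration for the synthetic gait-trajectory generator
#'
#' The generator emulates the three structural properties of optical gait
#' captures that the recovery models exploit: (1) strong correlation between
#' marker channels (a low-rank trajectory matrix), (2) periodic,
#' low-frequency trajectories, (3) a frequency support shared by all channels
#' (joint spectral sparsity). It is a latent-factor sinusoid model, not a
#' biomechanical simulation.
#'
#' @param n_markers Number of markers (default 37, a full-body marker set).
#' @param n_frames Number of frames (default 2400 = 10 cycles at the default
#'   cycle length). Choosing an integer multiple of `cycle_frames` makes the
#'   spectral support exact (no leakage).
#' @param frame_rate Hz (default 240).
#' @param cycle_frames Frames per gait cycle (default 240, i.e. a 1 s stride
#'   at 240 Hz).
#' @param n_harmonics Number of harmonics of the stride frequency present in
#'   every trajectory (default 4).
#' @param latent_rank Number of shared latent factors `k` (default 5); the
#'   noiseless matrix has rank `<= k`. Must satisfy
#'   `latent_rank <= 2 * n_harmonics`.
#' @param amplitude_range Range (mm) for harmonic amplitudes of the latent
#'   factors (default 10–50 mm, typical marker excursion scale).
#' @param offset_range Range (mm) of the static offsets, realized through the
#'   factors' DC components so the rank bound is preserved (default ±500 mm).
#' @param noise_sd Measurement noise standard deviation in mm (default 0).
#' @param rng_seed Integer seed; the generator is deterministic given it.
#' @return Object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_markers = 37L, n_frames = 2400L,
                            frame_rate = 240, cycle_frames = 240L,
                            n_harmonics = 4L, latent_rank = 5L,
                            amplitude_range = c(10, 50),
                            offset_range = c(-500, 500),
                            noise_sd = 0, rng_seed = 1L) {
  cfg <- list(n_markers = as.integer(n_markers), n_frames = as.integer(n_frames),
              frame_rate = frame_rate, cycle_frames = as.integer(cycle_frames),
              n_harmonics = as.integer(n_harmonics),
              latent_rank = as.integer(latent_rank),
              amplitude_range = amplitude_range, offset_range = offset_range,
              noise_sd = noise_sd, rng_seed = as.integer(rng_seed))
  if (cfg$latent_rank > 2L * cfg$n_harmonics) {
    stop("latent_rank must be <= 2 * n_harmonics (each shared frequency contributes a sine and a cosine)",
         call. = FALSE)
  }
  if (cfg$cycle_frames < 4L * cfg$n_harmonics) {
    stop("cycle_frames must be >= 4 * n_harmonics (highest harmonic below Nyquist)",
         call. = FALSE)
  }
  stopifnot(cfg$n_markers >= 1L, cfg$n_frames >= 2L, cfg$latent_rank >= 1L,
            cfg$noise_sd >= 0, length(cfg$amplitude_range) == 2L,
            cfg$amplitude_range[1] <= cfg$amplitude_range[2])
  structure(cfg, class = "gait_sim_config")
}

#' Generate synthetic marker trajectories
#'
#' Builds a shared basis of sines and cosines at the stride fundamental
#' `1/cycle_frames` and its first `n_harmonics` multiples (plus a constant
#' column), draws `latent_rank` latent factors as random phase/amplitude
#' combinations in that basis, and mixes them into `3 * n_markers` channels
#' with a random mixing matrix. Per-channel offsets come from the factors'
#' DC components, so the noiseless matrix has rank at most `latent_rank`
#' while every channel shares the same frequency support.
#'
#' @param cfg A [gait_sim_config()].
#' @return List with `observed` (a [trajectory_matrix()] including noise, if
#'   any) and `truth` (the noiseless ground truth).
#' @export
generate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  with_seed(cfg$rng_seed, {
    n <- cfg$n_frames
    H <- cfg$n_harmonics
    k <- cfg$latent_rank
    nch <- 3L * cfg$n_markers
    t0 <- 0:(n - 1L)

    basis <- matrix(1, n, 2L * H + 1L)
    for (h in seq_len(H)) {
      w <- 2 * pi * h / cfg$cycle_frames
      basis[, 2L * h] <- sin(w * t0)
      basis[, 2L * h + 1L] <- cos(w * t0)
    }

    loading <- matrix(0, k, 2L * H + 1L)
    loading[, 1L] <- stats::runif(k, cfg$offset_range[1], cfg$offset_range[2])
    for (j in seq_len(k)) {
      amp <- stats::runif(H, cfg$amplitude_range[1], cfg$amplitude_range[2])
      phi <- stats::runif(H, 0, 2 * pi)
      # a * sin(w t + phi) = a cos(phi) sin(w t) + a sin(phi) cos(w t)
      loading[j, 2L * seq_len(H)] <- amp * cos(phi)
      loading[j, 2L * seq_len(H) + 1L] <- amp * sin(phi)
    }

    mixing <- matrix(stats::rnorm(nch * k, sd = 1 / sqrt(k)), nch, k)
    clean <- basis %*% t(mixing %*% loading)  # n x nch

    markers <- sprintf("M%02d", seq_len(cfg$n_markers))
    truth <- trajectory_matrix(clean, cfg$frame_rate, markers)
    noisy <- clean
    if (cfg$noise_sd > 0) {
      noisy <- clean + matrix(stats::rnorm(n * nch, sd = cfg$noise_sd), n, nch)
    }
    list(observed = trajectory_matrix(noisy, cfg$frame_rate, markers),
         truth = truth)
  })
}

#' Gap-simulation protocol
#'
#' @param n_gaps_range Integer interval for the number of gaps per run
#'   (default 5–20).
#' @param gap_fraction_range Gap length as a fraction of one gait cycle
#'   (default 0.10–0.50).
#' @param repetitions Number of repetitions of the whole experiment
#'   (default 20); used by [run_experiment()].
#' @param rng_seed Integer seed.
#' @return Object of class `gap_spec`.
#' @export
gap_spec <- function(n_gaps_range = c(5L, 20L),
                     gap_fraction_range = c(0.10, 0.50),
                     repetitions = 20L, rng_seed = 1L) {
  stopifnot(length(n_gaps_range) == 2L, n_gaps_range[1] >= 1L,
            n_gaps_range[1] <= n_gaps_range[2],
            length(gap_fraction_range) == 2L, gap_fraction_range[1] > 0,
            gap_fraction_range[1] <= gap_fraction_range[2],
            gap_fraction_range[2] <= 1, repetitions >= 1L)
  structure(
    list(n_gaps_range = as.integer(n_gaps_range),
         gap_fraction_range = gap_fraction_range,
         repetitions = as.integer(repetitions),
         rng_seed = as.integer(rng_seed)),
    class = "gap_spec"
  )
}

#' Punch synthetic occlusion gaps into a trajectory matrix
#'
#' Draws a gap count uniformly from `spec$n_gaps_range`; each gap picks a
#' marker uniformly, a length uniformly from
#' `spec$gap_fraction_range * cycle_frames` (rounded, at least 1 frame) and a
#' uniform start so the gap fits, then removes all three coordinates of that
#' marker over the interval (occlusion loses the whole 3D position).
#' Overlapping gaps on one marker merge. Deterministic given
#' `spec$rng_seed`.
#'
#' @param truth A [trajectory_matrix()] (fully observed).
#' @param spec A [gap_spec()].
#' @param cycle_frames Frames per gait cycle, the unit for gap lengths.
#' @return List with `gapped` (the trajectory with `NA` at missing entries),
#'   `mask` (an [observation_mask()]) and `gaps`, a data frame of merged
#'   missing intervals `(marker, start_frame, end_frame)` using 0-based,
#'   half-open `[start, end)` frame indices. The raw pre-merge draws are kept
#'   in `attr(gaps, "draws")`.
#' @export
simulate_gaps <- function(truth, spec, cycle_frames) {
  stopifnot(inherits(truth, "trajectory_matrix"), inherits(spec, "gap_spec"))
  n <- nrow(truth$values)
  m <- length(truth$marker_names)
  cycle_frames <- as.integer(cycle_frames)
  if (cycle_frames > n) stop("cycle_frames exceeds the number of frames", call. = FALSE)
  max_len <- max(1L, round(spec$gap_fraction_range[2] * cycle_frames))
  if (max_len > n) stop("gap length can exceed the trajectory length", call. = FALSE)

  with_seed(spec$rng_seed, {
    g <- sample(spec$n_gaps_range[1]:spec$n_gaps_range[2], 1L)
    marker <- sample.int(m, g, replace = TRUE)
    frac <- stats::runif(g, spec$gap_fraction_range[1], spec$gap_fraction_range[2])
    len <- pmax(1L, as.integer(round(frac * cycle_frames)))
    start <- vapply(len, function(L) sample(0:(n - L), 1L), integer(1))

    vals <- truth$values
    obs <- matrix(TRUE, n, ncol(vals))
    for (i in seq_len(g)) {
      rows <- (start[i] + 1L):(start[i] + len[i])
      ch <- marker_channels(marker[i])
      vals[rows, ch] <- NA_real_
      obs[rows, ch] <- FALSE
    }

    gaps <- merged_gap_manifest(obs, truth$marker_names)
    attr(gaps, "draws") <- data.frame(marker = marker, start_frame = start,
                                      length = len)
    gapped <- truth
    gapped$values <- vals
    list(gapped = gapped, mask = observation_mask(obs), gaps = gaps)
  })
}

# Merged missing intervals per marker, 0-based half-open [start, end).
merged_gap_manifest <- function(obs, marker_names) {
  out <- list()
  for (k in seq_along(marker_names)) {
    miss <- !obs[, marker_channels(k)[1]]
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        marker = marker_names[k],
        start_frame = starts[keep],
        end_frame = ends[keep]
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(marker = character(), start_frame = integer(),
                      end_frame = integer()))
  }
  do.call(rbind, out)
}
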