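#' Marker trajectory matrix
#'
#' Container for a block of 3D optical motion-capture data: `n_frames` time
#' samples of `m` markers, stored as an `n_frames x 3m` numeric matrix in
#' millimetres. For marker `k` the three consecutive columns
#' `3(k-1)+1 .. 3(k-1)+3` hold its x, y and z coordinates, so each column is
#' one coordinate channel's time series. Missing samples are `NA`/`NaN`.
#'
#' @param values Numeric matrix, `n_frames x 3m`, millimetres. `NA`/`NaN`
#'   entries denote missing samples.
#' @param frame_rate Sampling rate in Hz (frames per second).
#' @param marker_names Character vector of `m` marker labels.
#' @return An object of class `trajectory_matrix` with fields `values`,
#'   `frame_rate` and `marker_names`.
#' @examples
#' tm <- trajectory_matrix(matrix(rnorm(60), 10, 6), 240, c("LHEE", "RHEE"))
#' channel_names(tm)
#' @export
trajectory_matrix <- function(values, frame_rate, marker_names) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) {
    stop("a trajectory matrix needs at least 2 frames", call. = FALSE)
  }
  if (!is.character(marker_names) || anyDuplicated(marker_names)) {
    stop("'marker_names' must be unique character labels", call. = FALSE)
  }
  if (ncol(values) != 3L * length(marker_names)) {
    stop(sprintf(
      "expected %d channels (3 per marker) but 'values' has %d columns",
      3L * length(marker_names), ncol(values)
    ), call. = FALSE)
  }
  if (!(is.numeric(frame_rate) && length(frame_rate) == 1L && frame_rate > 0)) {
    stop("'frame_rate' must be a single positive number (Hz)", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("observed entries must be finite (use NA/NaN for missing)", call. = FALSE)
  }
  colnames(values) <- channel_labels(marker_names)
  structure(
    list(values = values, frame_rate = frame_rate, marker_names = marker_names),
    class = "trajectory_matrix"
  )
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  n_miss <- sum(!is.finite(x$values))
  cat(sprintf(
    "<trajectory_matrix> %d frames x %d markers (%d channels) @ %g Hz, %d missing entries\n",
    nrow(x$values), length(x$marker_names), ncol(x$values), x$frame_rate, n_miss
  ))
  invisible(x)
}

#' @export
dim.trajectory_matrix <- function(x) dim(x$values)

channel_labels <- function(marker_names) {
  paste0(rep(marker_names, each = 3L), c("_x", "_y", "_z"))
}

#' Column indices of one marker's x/y/z channels
#'
#' @param k Marker index (1-based).
#' @return Integer vector of the three channel (column) indices.
#' @export
marker_channels <- function(k) {
  3L * (as.integer(k) - 1L) + 1:3
}

#' Observation mask
#'
#' Boolean matrix marking which entries of a [trajectory_matrix()] were
#' actually measured (`TRUE` = observed). Recovery never alters observed
#' entries; only `FALSE` positions are estimated.
#'
#' @param observed Logical matrix, same shape as the trajectory values.
#' @return Object of class `observation_mask` with field `observed`.
#' @seealso [mask_from_values()] to derive the mask from NA positions.
#' @export
observation_mask <- function(observed) {
  observed <- as.matrix(observed)
  if (!is.logical(observed) || anyNA(observed)) {
    stop("'observed' must be a logical matrix without NA", call. = FALSE)
  }
  dimnames(observed) <- NULL
  structure(list(observed = observed), class = "observation_mask")
}

#' Derive the observation mask from missing values
#'
#' Non-finite entries (`NA`, `NaN`, `Inf`) are treated as missing. Because an
#' occluded marker loses its whole 3D position, any marker-frame with at least
#' one missing coordinate is demoted to fully missing (atomicity).
#'
#' @param tm A [trajectory_matrix()].
#' @return An [observation_mask()].
#' @export
mask_from_values <- function(tm) {
  stopifnot(inherits(tm, "trajectory_matrix"))
  obs <- is.finite(tm$values)
  m <- length(tm$marker_names)
  for (k in seq_len(m)) {
    ch <- marker_channels(k)
    partial <- !(rowSums(obs[, ch, drop = FALSE]) %in% c(0L, 3L))
    if (any(partial)) obs[partial, ch] <- FALSE
  }
  observation_mask(obs)
}

check_mask <- function(tm, mask) {
  if (is.null(mask)) mask <- mask_from_values(tm)
  stopifnot(inherits(mask, "observation_mask"))
  if (!identical(dim(mask$observed), dim(tm$values))) {
    stop("mask shape does not match the trajectory matrix", call. = FALSE)
  }
  if (any(!is.finite(tm$values[mask$observed]))) {
    stop("non-finite values at observed positions", call. = FALSE)
  }
  mask
}

# Channels with no observation at all cannot be recovered by any method here.
check_recoverable <- function(tm, mask) {
  n_obs <- colSums(mask$observed)
  if (any(n_obs == 0L)) {
    bad <- colnames(tm$values)[n_obs == 0L]
    if (is.null(bad)) bad <- which(n_obs == 0L)
    stop(sprintf(
      "channel(s) with no observed entries cannot be recovered: %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

# Per-channel linear interpolation of missing entries, endpoints held constant.
# Used as the deterministic initialization of both solvers.
interp_init <- function(values, observed) {
  out <- values
  n <- nrow(values)
  for (j in seq_len(ncol(values))) {
    idx <- which(observed[, j])
    if (length(idx) == n) next
    if (length(idx) == 1L) {
      out[, j] <- values[idx, j]
    } else {
      out[, j] <- stats::approx(idx, values[idx, j], xout = seq_len(n),
                                method = "linear", rule = 2)$y
    }
    out[idx, j] <- values[idx, j]
  }
  out
}
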