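#' Spectral penalty weights
#'
#' Builds the diagonal weight matrix applied to the Fourier spectrum before
#' the sparsity norm. Bins above the cut-off `threshold_bin` get
#' `high_weight` (default 100) and are strongly shrunk; bins at or below it
#' get `low_weight` (default 1), leaving the physiological low-frequency
#' content of gait nearly unpenalized. Because a real signal's spectrum is
#' conjugate-symmetric, the rule is applied to the folded bin index
#' `min(i, n_frames - i)` (0-based), so mirror bins always share a weight and
#' reconstructions stay real.
#'
#' @param n_frames Number of time samples (= number of DFT bins).
#' @param threshold_bin Cut-off as a folded bin index (default 100).
#' @param high_weight,low_weight Penalty weights above/below the cut-off.
#' @param threshold_hz Optional cut-off in Hz; converted to a bin index via
#'   `floor(threshold_hz * n_frames / frame_rate)` and overriding
#'   `threshold_bin`. Requires `frame_rate`.
#' @param frame_rate Sampling rate in Hz, needed only with `threshold_hz`.
#' @return Object of class `spectral_weights` with fields `weights` (length
#'   `n_frames`), `threshold_bin`, `high_weight`, `low_weight`.
#' @examples
#' w <- spectral_weights(240, threshold_bin = 20)
#' table(w$weights)
#' @export
spectral_weights <- function(n_frames, threshold_bin = 100, high_weight = 100,
                             low_weight = 1, threshold_hz = NULL,
                             frame_rate = NULL) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 2L, high_weight >= 0, low_weight >= 0)
  if (!is.null(threshold_hz)) {
    if (is.null(frame_rate)) {
      stop("'frame_rate' is required to convert 'threshold_hz' to a bin index",
           call. = FALSE)
    }
    threshold_bin <- floor(threshold_hz * n_frames / frame_rate)
  }
  bins <- 0:(n_frames - 1L)
  folded <- pmin(bins, n_frames - bins)
  w <- ifelse(folded > threshold_bin, high_weight, low_weight)
  structure(
    list(weights = as.numeric(w), threshold_bin = as.integer(threshold_bin),
         high_weight = high_weight, low_weight = low_weight,
         n_frames = n_frames),
    class = "spectral_weights"
  )
}

#' @export
print.spectral_weights <- function(x, ...) {
  cat(sprintf(
    "<spectral_weights> %d bins, cut-off at folded bin %d (%d high-penalty bins: w=%g, else w=%g)\n",
    x$n_frames, x$threshold_bin, sum(x$weights == x$high_weight & x$high_weight != x$low_weight),
    x$high_weight, x$low_weight
  ))
  invisible(x)
}
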