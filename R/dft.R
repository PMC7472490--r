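#' Unitary discrete Fourier transform of each column
#'
#' Applies the DFT down each column (one coordinate channel's time series per
#' column) with the unitary `1/sqrt(n)` scaling, so the transform preserves
#' Frobenius norm and its inverse is its conjugate transpose. Row `i` of the
#' output is frequency bin `i - 1`; the bin indexing matches
#' [spectral_weights()].
#'
#' @param m Real or complex matrix (or vector, treated as one column) with
#'   `n_frames` rows.
#' @return Complex matrix of the same shape.
#' @examples
#' x <- matrix(rnorm(24), 8, 3)
#' max(Mod(unitary_idft(unitary_dft(x)) - x)) # ~ 1e-16
#' @export
unitary_dft <- function(m) {
  m <- as_finite_matrix(m)
  stats::mvfft(m) / sqrt(nrow(m))
}

#' @rdname unitary_dft
#' @export
unitary_idft <- function(m) {
  m <- as_finite_matrix(m)
  stats::mvfft(m, inverse = TRUE) / sqrt(nrow(m))
}

as_finite_matrix <- function(m) {
  m <- as.matrix(m)
  ok <- if (is.complex(m)) is.finite(Re(m)) & is.finite(Im(m)) else is.finite(m)
  if (!all(ok)) stop("input contains non-finite entries", call. = FALSE)
  m
}
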