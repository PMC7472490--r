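#' Soft-thresholding (proximal operator of the l1 norm)
#'
#' Shrinks the magnitude of each entry by `gamma` and clips at zero while
#' preserving the phase: `max(|c| - gamma, 0) * c / |c|`, with 0 mapped to 0.
#' For real input this is the familiar `sign(c) * max(|c| - gamma, 0)`; the
#' magnitude form extends it to the complex Fourier coefficients shrunk by the
#' spectral prior.
#'
#' @param x Real or complex scalar, vector or matrix.
#' @param gamma Non-negative threshold; a scalar or an array conformable with
#'   `x` (per-entry thresholds).
#' @return Same shape and mode as `x`.
#' @examples
#' soft_threshold(c(-3, 1, 3), 1)        # -2, 0, 2
#' soft_threshold(3 + 4i, 1)             # 2.4 + 3.2i
#' @export
soft_threshold <- function(x, gamma) {
  if (any(gamma < 0)) stop("'gamma' must be non-negative", call. = FALSE)
  if (!(length(gamma) == 1L || length(gamma) == length(x))) {
    stop("'gamma' must be a scalar or conformable with 'x'", call. = FALSE)
  }
  mag <- Mod(x)
  shrunk <- pmax(mag - gamma, 0)
  scale <- shrunk / mag
  scale[mag == 0] <- 0
  out <- x * scale
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Singular-value thresholding (proximal operator of the nuclear norm)
#'
#' Computes `U soft_threshold(Sigma, gamma) V'` from the SVD `M = U Sigma V'`.
#' This is the exact minimizer of `||Q||_* + 1/(2 gamma) ||Q - M||_F^2`; the
#' result's singular values are `max(sigma_i - gamma, 0)`, so its rank never
#' exceeds `rank(M)`.
#'
#' @param m Real matrix with finite entries.
#' @param gamma Non-negative scalar threshold.
#' @return Real matrix of the same shape.
#' @examples
#' svt(diag(c(3, 1)), 2)  # diag(1, 0)
#' @export
svt <- function(m, gamma) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("'m' must be finite", call. = FALSE)
  if (!(is.numeric(gamma) && length(gamma) == 1L && gamma >= 0)) {
    stop("'gamma' must be a single non-negative number", call. = FALSE)
  }
  s <- robust_svd(m)
  d <- pmax(s$d - gamma, 0)
  s$u %*% (d * t(s$v))
}

# LAPACK's divide-and-conquer SVD (dgesdd) occasionally fails to converge on
# valid input; retry on the transpose, then fall back to an eigendecomposition
# of the Gram matrix.
robust_svd <- function(m) {
  tryCatch(svd(m), error = function(e1) {
    tryCatch({
      s <- svd(t(m))
      list(d = s$d, u = s$v, v = s$u)
    }, error = function(e2) {
      wide <- ncol(m) >= nrow(m)
      g <- if (wide) tcrossprod(m) else crossprod(m)
      e <- eigen(g, symmetric = TRUE)
      d <- sqrt(pmax(e$values, 0))
      pos <- d > max(d[1], .Machine$double.eps) * 1e-12
      if (wide) {
        u <- e$vectors
        v <- crossprod(m, u)
        v[, pos] <- sweep(v[, pos, drop = FALSE], 2L, d[pos], `/`)
        list(d = d, u = u, v = v)
      } else {
        v <- e$vectors
        u <- m %*% v
        u[, pos] <- sweep(u[, pos, drop = FALSE], 2L, d[pos], `/`)
        list(d = d, u = u, v = v)
      }
    })
  })
}

# Row-wise group shrinkage: prox of sum_i t_i ||r_i||_2 at C, one threshold
# per row. Zero rows map to zero.
group_shrink_rows <- function(C, thresholds) {
  rn <- sqrt(rowSums(Mod(C)^2))
  scale <- pmax(rn - thresholds, 0)
  nz <- rn > 0
  scale[nz] <- scale[nz] / rn[nz]
  scale[!nz] <- 0
  C * scale
}

nuclear_norm <- function(m) {
  sum(tryCatch(svd(m, nu = 0, nv = 0)$d, error = function(e) robust_svd(m)$d))
}

fro <- function(m) sqrt(sum(Mod(m)^2))
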