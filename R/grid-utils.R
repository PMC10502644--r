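# Small grid helpers shared by the wave-field simulator, the inversion
# and the map features. All operate on plain matrices (rows = y).

#' Gaussian smoothing of a matrix
#'
#' Separable Gaussian convolution with reflective (symmetric) border
#' handling. Complex matrices are smoothed component-wise.
#'
#' @param m numeric or complex matrix.
#' @param sigma kernel standard deviation in pixels; `0` is a no-op.
#' @return matrix of the same dimension.
#' @export
gaussian_smooth <- function(m, sigma = 1) {
  if (sigma <= 0) return(m)
  if (is.complex(m)) {
    return(gaussian_smooth(Re(m), sigma) +
             1i * gaussian_smooth(Im(m), sigma))
  }
  rad <- max(1L, ceiling(3 * sigma))
  x <- seq(-rad, rad)
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(v[rad:1], v, v[n:(n - rad + 1)])
    stats::filter(vp, kern, sides = 2)[(rad + 1):(rad + n)]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(t(m2), 2, pad_conv))
}

#' Five-point Laplacian of a matrix
#'
#' Spacing-aware second-difference stencil; the one-pixel border is
#' returned as `NA` (complex input: `NA` in both components).
#'
#' @param m numeric or complex matrix.
#' @param h grid spacing in m.
#' @return matrix of the same dimension.
#' @export
laplacian5 <- function(m, h = 1) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(if (is.complex(m)) NA_complex_ else NA_real_, nr, nc)
  i <- 2:(nr - 1)
  j <- 2:(nc - 1)
  out[i, j] <- (m[i - 1, j] + m[i + 1, j] + m[i, j - 1] + m[i, j + 1] -
                  4 * m[i, j]) / h^2
  out
}

# Bilinear interpolation of matrix `m` at fractional (row, col)
# positions. Out-of-grid points return NA.
.bilinear <- function(m, row, col) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- rep(NA_real_, length(row))
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc &
    is.finite(row) & is.finite(col)
  r0 <- pmin(floor(row[ok]), nr - 1)
  c0 <- pmin(floor(col[ok]), nc - 1)
  fr <- row[ok] - r0
  fc <- col[ok] - c0
  out[ok] <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
    fr * (1 - fc) * m[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * m[cbind(r0, c0 + 1)] +
    fr * fc * m[cbind(r0 + 1, c0 + 1)]
  out
}
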